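test_that("every generator is a pure function of parameters and seed", {
    a <- simulatePhosphoCounts(nProteins = 20, seed = 71)
    b <- simulatePhosphoCounts(nProteins = 20, seed = 71)
    expect_identical(assay(a$counts, "counts"), assay(b$counts, "counts"))
    expect_identical(a$truth, b$truth)

    n1 <- simulateNetwork(c(8, 8), seed = 72)
    n2 <- simulateNetwork(c(8, 8), seed = 72)
    expect_identical(edgeTable(n1$network), edgeTable(n2$network))

    e1 <- simulateExonData(nGenes = 15, seed = 73)
    e2 <- simulateExonData(nGenes = 15, seed = 73)
    expect_identical(assay(e1$probes, "log2intensity"),
                     assay(e2$probes, "log2intensity"))

    g <- sprintf("g%02d", 1:50)
    a1 <- simulateAnnotations(g, nTerms = 5, termSizeRange = c(3, 10),
                              seed = 74)
    a2 <- simulateAnnotations(g, nTerms = 5, termSizeRange = c(3, 10),
                              seed = 74)
    expect_identical(geneSets(a1$annotations), geneSets(a2$annotations))
})

test_that("generated datasets satisfy the container invariants", {
    expect_true(validObject(
        simulatePhosphoCounts(nProteins = 15, seed = 75)$counts))
    expect_true(validObject(simulateNetwork(c(5, 5), seed = 75)$network))
    expect_true(validObject(simulateExonData(nGenes = 10, seed = 75)$probes))
    expect_true(validObject(
        simulateAnnotations(sprintf("g%d", 1:30), nTerms = 4,
                            termSizeRange = c(3, 8),
                            seed = 75)$annotations))
})

test_that("null phospho simulations stay below the false-positive budget", {
    sim <- simulatePhosphoCounts(nProteins = 300, fractionDifferential = 0,
                                 baselineMean = 20, dispersion = 5,
                                 seed = 76)
    agg <- aggregateRuns(sim$counts)
    fp <- sapply(defaultComparisons(), function(cmp)
        mean(siteChanges(agg, cmp)$score != 0))
    expect_true(all(fp <= 0.05))
})

test_that("planted phosphosites score in the planted direction", {
    sim <- simulatePhosphoCounts(nProteins = 300, effectFold = 10,
                                 baselineMean = 20, seed = 77)
    agg <- aggregateRuns(sim$counts)
    tr <- sim$truth$sites[sim$truth$sites$differential, ]
    hit <- logical(nrow(tr))
    for (cmp in unique(tr$comparison)) {
        ch <- siteChanges(agg, cmp)
        idx <- tr$comparison == cmp
        m <- match(paste(tr$protein_id, tr$site_id)[idx],
                   paste(ch$protein_id, ch$site_id))
        hit[idx] <- ch$score[m] == tr$direction[idx]
    }
    expect_gte(mean(hit), 0.95)
})

test_that("planted-partition networks have the expected edge structure", {
    # no cross edges when pOut = 0: every component sits inside one block
    sim <- simulateNetwork(c(10, 10, 1), pIn = 0.8, pOut = 0, seed = 78)
    memb <- igraph::components(networkGraph(sim$network))$membership
    block <- sim$truth$nodes$block
    for (comp in unique(memb))
        expect_equal(length(unique(block[memb == comp])), 1L)
    # a block of size 1 is an isolated node
    expect_equal(igraph::degree(networkGraph(sim$network))[["N0021"]], 0)

    # mean edge count over seeds matches the closed-form expectation
    sizes <- c(12, 8); pIn <- 0.5; pOut <- 0.05
    exp_edges <- sum(choose(sizes, 2)) * pIn + prod(sizes) * pOut
    got <- mean(sapply(1:50, function(s)
        nrow(edgeTable(simulateNetwork(sizes, pIn, pOut,
                                       seed = 1000 + s)$network))))
    expect_lt(abs(got - exp_edges) / exp_edges, 0.1)
})

test_that("noise-free unspliced exon data is exactly flat", {
    sim <- simulateExonData(nGenes = 10, fractionSpliced = 0, noiseSd = 0,
                            seed = 79)
    sv <- spliceVariation(sim$probes, "CA1a/AT")
    expect_equal(sv$sd, rep(0, nrow(sv)))
    expect_equal(sv$mean_delta, rep(0, nrow(sv)))
})

test_that("a noise-free spliced gene matches the hand-computed ramp SD", {
    sim <- simulateExonData(nGenes = 1, probesPerGeneRange = c(9, 9),
                            fractionSpliced = 1, noiseSd = 0,
                            divergenceAmplitude = 2, foldCoupling = 3,
                            junctionFraction = 0, seed = 80)
    d <- probeDeltas(sim$probes, "G0001", "CA1a/AT")
    # ramp: 0 at the 5'-most probe down to -2*amplitude at the 3' end,
    # plus the whole-gene fold-coupling shift (which cannot move the SD)
    ramp <- -4 * (0:8) / 8 - 3
    expect_equal(unname(d), ramp, tolerance = 1e-9)
    expect_equal(spliceSD(d), oracleSD(ramp), tolerance = 1e-9)
    expect_gte(spliceSD(d), 1)
})

test_that("annotation simulation respects sizes and the planted subset", {
    g <- sprintf("g%03d", 1:200)
    empty <- simulateAnnotations(g, nTerms = 0, seed = 81)
    expect_length(geneSets(empty$annotations), 0L)

    sim <- simulateAnnotations(g, nTerms = 20, termSizeRange = c(5, 15),
                               seed = 82)
    expect_true(all(lengths(geneSets(sim$annotations)) >= 5))
    expect_true(all(lengths(geneSets(sim$annotations)) <= 15))

    sub <- g[1:40]
    pl <- simulateAnnotations(g, nTerms = 5, termSizeRange = c(10, 30),
                              plantedTermIn = sub, seed = 83)
    members <- geneSets(pl$annotations)[[pl$truth$planted_term]]
    expect_gte(mean(members %in% sub), 0.9)
})

test_that("writeSimulation emits the dataset, truth tables and parameters", {
    dir <- withr::local_tempdir()
    sim <- simulateExonData(nGenes = 6, seed = 84)
    paths <- writeSimulation(sim, dir, prefix = "exon")
    expect_true(file.exists(file.path(dir, "exon_probes.tsv")))
    expect_true(file.exists(file.path(dir, "exon_truth_genes.tsv")))
    expect_true(file.exists(file.path(dir, "exon_params.yaml")))
    params <- yaml::read_yaml(file.path(dir, "exon_params.yaml"))
    expect_equal(params$seed, 84)
    back <- readExonProbes(file.path(dir, "exon_probes.tsv"))
    expect_equal(assay(back, "log2intensity"),
                 assay(sim$probes, "log2intensity"), tolerance = 1e-10)
})
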