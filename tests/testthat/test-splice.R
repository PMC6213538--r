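makeGene <- function(intA, intB, probeType = NULL, reps = 3, noise = 0) {
    # one gene; intA/intB are per-probe true levels in conditions A and B
    n <- length(intA)
    if (is.null(probeType)) probeType <- rep("coding_exon", n)
    ints <- cbind(matrix(rep(intA, reps), n) + noise,
                  matrix(rep(intB, reps), n) + noise)
    ExonProbeSet(ints, genes = rep("G1", n),
                 probes = sprintf("p%d", 1:n),
                 probeIndex = 1:n, probeType = probeType,
                 condition = rep(c("A", "B"), each = reps),
                 replicate = rep(sprintf("r%d", 1:reps), 2))
}

test_that("probe deltas subtract replicate means in probe order", {
    x <- makeGene(c(8, 9, 10, 11), c(8, 8, 8, 8))
    expect_equal(unname(probeDeltas(x, "G1", "A/B")), c(0, 1, 2, 3))
    # identical conditions give all-zero deltas
    y <- makeGene(c(5, 6, 7), c(5, 6, 7))
    expect_equal(unname(probeDeltas(y, "G1", "A/B")), c(0, 0, 0))
})

test_that("probe deltas agree with a spreadsheet-style recomputation", {
    set.seed(41)
    n <- 4
    ints <- matrix(stats::rnorm(n * 6, 8, 1), n)
    x <- ExonProbeSet(ints, genes = rep("G1", n),
                      probes = sprintf("p%d", 1:n), probeIndex = 1:n,
                      probeType = rep("coding_exon", n),
                      condition = rep(c("A", "B"), each = 3),
                      replicate = rep(sprintf("r%d", 1:3), 2))
    manual <- sapply(1:n, function(i)
        sum(ints[i, 1:3]) / 3 - sum(ints[i, 4:6]) / 3)
    expect_equal(unname(probeDeltas(x, "G1", "A/B")), manual,
                 tolerance = 1e-12)
})

test_that("junction probes are excluded and short genes are skipped", {
    x <- makeGene(c(8, 9, 10, 11, 12), c(8, 8, 8, 8, 8),
                  probeType = c("coding_exon", "junction", "coding_exon",
                                "coding_exon", "junction"))
    d <- probeDeltas(x, "G1", "A/B")
    expect_equal(names(d), c("p1", "p3", "p4"))
    short <- makeGene(c(8, 9, 10), c(8, 8, 8),
                      probeType = c("coding_exon", "junction", "junction"))
    expect_message(res <- probeDeltas(short, "G1", "A/B"), "skipped")
    expect_null(res)
    expect_error(probeDeltas(x, "NOPE", "A/B"), "not found")
})

test_that("splice SD is the sample SD and is shift invariant", {
    expect_equal(spliceSD(c(0, 0, 0)), 0)
    expect_equal(spliceSD(c(0, 0, 3)), sqrt(3), tolerance = 1e-12)
    expect_equal(round(spliceSD(c(0, 0, 3)), 3), 1.732)
    for (c0 in c(-7, 0.3, 12))
        expect_equal(spliceSD(rep(c0, 4)), 0)
    expect_error(spliceSD(c(1, 2)), "at least 3")
    set.seed(42)
    for (i in 1:100) {
        v <- stats::rnorm(sample(3:30, 1), sd = sample(1:5, 1))
        expect_equal(spliceSD(v), spliceSD(v + 3.7), tolerance = 1e-9)
    }
})

test_that("splice SD equals a two-pass oracle on 10^4 random vectors", {
    set.seed(43)
    for (i in seq_len(1e4)) {
        v <- stats::rnorm(3 + i %% 20, mean = i %% 7, sd = 1 + i %% 3)
        expect_equal(spliceSD(v), oracleSD(v), tolerance = 1e-12)
    }
})

test_that("swapping comparison direction keeps SD, negates signed fold", {
    sim <- simulateExonData(nGenes = 40, fractionSpliced = 0.2, seed = 44)
    fwd <- spliceVariation(sim$probes, "CA1a/AT")
    rev <- spliceVariation(sim$probes, "AT/CA1a")
    expect_equal(rev$sd, fwd$sd, tolerance = 1e-12)
    expect_equal(rev$mean_delta, -fwd$mean_delta, tolerance = 1e-12)
    big <- abs(fwd$signed_fold) > 1 + 1e-9
    expect_equal(rev$signed_fold[big], -fwd$signed_fold[big],
                 tolerance = 1e-12)
})

test_that("pure expression shifts always land in the [0,1) SD bin", {
    for (shift in c(0.1, 2, 8)) {
        x <- makeGene(c(8, 9, 7, 10) + shift, c(8, 9, 7, 10))
        sv <- spliceVariation(x, "A/B")
        expect_equal(sv$sd, 0)
        b <- binBySd(sv)
        expect_equal(b$percent[b$bin == "[0,1)"], 100)
    }
})

test_that("SD bin percentages partition the cohort", {
    set.seed(45)
    sv <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     comparison = "A/B",
                     n_probes = 5,
                     sd = stats::rexp(200, 1),
                     mean_delta = stats::rnorm(200))
    sv$signed_fold <- signedFold(sv$mean_delta)
    b <- binBySd(sv)
    expect_equal(sum(b$percent), 100, tolerance = 1e-9)
    expect_equal(sum(b$n_genes), 200L)
    expect_equal(nrow(binBySd(sv[0, ])), 0L)
})

test_that("large planted folds confined to high-SD genes produce the
           characteristic decreasing bin means", {
    lowA <- simulateExonData(nGenes = 300, fractionSpliced = 0,
                             noiseSd = 0.25, seed = 46)
    mid <- simulateExonData(nGenes = 60, fractionSpliced = 1,
                            divergenceAmplitude = 1.2, foldCoupling = 0,
                            noiseSd = 0.25, seed = 47)
    high <- simulateExonData(nGenes = 20, fractionSpliced = 1,
                             divergenceAmplitude = 4, foldCoupling = 5,
                             noiseSd = 0.25, seed = 48)
    svs <- mapply(function(sim, tag) {
        sv <- spliceVariation(sim$probes, "CA1a/AT")
        sv$gene_id <- paste0(tag, sv$gene_id)
        sv
    }, list(lowA, mid, high), c("a", "b", "c"), SIMPLIFY = FALSE)
    b <- binBySd(do.call(rbind, svs))
    expect_true(all(b$n_genes > 0))
    expect_true(all(diff(b$mean_signed_fold) < 0))
    expect_lt(b$mean_signed_fold[3], -20)
})

test_that("rank-sum comparison of SD distributions behaves at the limits", {
    x <- c(1.2, 1.5, 2, 3.1)
    expect_equal(compareSdDistributions(x, x)$p, 1)
    set.seed(49)
    a <- stats::rexp(200) + 1
    expect_lt(compareSdDistributions(a + 2, a)$p, 1e-6)
    expect_error(compareSdDistributions(c(0.2, 0.4), c(2, 3)), "SD >= 1")
})

test_that("rank-sum p agrees with exhaustive enumeration for small n", {
    set.seed(50)
    for (i in 1:20) {
        n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
        a <- stats::rnorm(n1, 5); b <- stats::rnorm(n2, 5.5)
        got <- compareSdDistributions(a, b, restrictMinSd = 0)$p
        expect_equal(got, oracleWilcoxExact(a, b), tolerance = 1e-6)
    }
})

test_that("top-fold enrichment uses the hypergeometric upper tail", {
    mk <- function(sd, fold) {
        data.frame(gene_id = sprintf("g%03d", seq_along(sd)),
                   comparison = "A/B", n_probes = 5, sd = sd,
                   mean_delta = log2(abs(fold)) * sign(fold),
                   signed_fold = fold)
    }
    allHigh <- mk(rep(1.5, 150), seq(2, 300, by = 2))
    r <- topFoldEnrichment(allHigh, topN = 100)
    expect_equal(r$proportion, 1)
    expect_equal(r$p, 1)

    # top 100 all high-SD against a 4% background rate
    sd <- c(rep(2, 100), rep(0.2, 2400))
    fold <- c(seq(1000, 1099), seq(2, 2401) / 1000 + 1)
    r2 <- topFoldEnrichment(mk(sd, fold), topN = 100)
    expect_equal(r2$proportion, 1)
    expect_equal(r2$p, oracleHyperTail(100, 100, 100, 2500),
                 tolerance = 1e-10)

    # disjoint high-fold and high-SD genes
    r3 <- topFoldEnrichment(mk(c(rep(0.1, 100), rep(3, 100)),
                               c(seq(500, 599), rep(1, 100))), topN = 100)
    expect_equal(r3$proportion, 0)
    expect_error(topFoldEnrichment(allHigh, topN = 0), "positive")
    expect_error(topFoldEnrichment(allHigh, topN = 1000), "at least")
})

test_that("positional grouping splits middle probes into thirds", {
    expect_equal(SpliceRewire:::.positionGroups(8, 3),
                 c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
    expect_equal(SpliceRewire:::.positionGroups(9, 3),
                 c(1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
    expect_equal(SpliceRewire:::.positionGroups(5, 3), 1:5)
})

test_that("positional profiles are flat for constant deltas and capture
           planted 3' divergence", {
    flat <- makeGene(rep(9, 8) + 1.5, rep(9, 8))
    # noise-free constant deltas make the ANOVA fit exact; only the group
    # means matter here
    pf <- suppressWarnings(positionalProfile(flat, "G1", "A/B"))
    expect_equal(unname(pf$profile$mean), rep(1.5, 5), tolerance = 1e-12)

    sim <- simulateExonData(nGenes = 120, fractionSpliced = 0.15,
                            probesPerGeneRange = c(8, 12),
                            junctionFraction = 0, seed = 51)
    sv <- spliceVariation(sim$probes, "CA1a/AT")
    prof <- sv[sv$n_probes >= 5, ]
    top <- prof$gene_id[order(-prof$sd)][1:10]
    pp <- positionalProfile(sim$probes, top, "CA1a/AT")
    expect_true(all(diff(pp$profile$mean) < 0))
    expect_lt(pp$anova$p, 0.05)
})

test_that("more planted spliced genes means more high-SD genes", {
    counts <- sapply(c(0.05, 0.15, 0.3), function(f) {
        sim <- simulateExonData(nGenes = 250, fractionSpliced = f,
                                seed = 52)
        sv <- spliceVariation(sim$probes, "CA1a/AT")
        sum(sv$sd >= 1)
    })
    expect_true(all(diff(counts) > 0))
})

test_that("the SD >= 1 rule recovers planted spliced genes", {
    sim <- simulateExonData(nGenes = 250, fractionSpliced = 0.1, seed = 53)
    sv <- spliceVariation(sim$probes, "CA1a/AT")
    tr <- merge(sv, sim$truth$genes, by = "gene_id")
    expect_gte(mean(tr$sd[tr$spliced] >= 1), 0.95)
    expect_gte(mean(tr$sd[!tr$spliced] < 1), 0.95)
})
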