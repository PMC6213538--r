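#' Default cell-line panel and comparisons
#'
#' The four conditions of the breast tumorigenic-progression panel
#' (MCF10A-lineage naming: 10A, AT, TG3B, CA1a) and the three pairwise
#' comparisons that follow its derivation history: AT vs 10A, TG3B vs AT
#' and CA1a vs AT, written \code{"numerator/denominator"}.
#'
#' @return character vector.
#' @export
defaultConditions <- function() c("10A", "AT", "TG3B", "CA1a")

#' @rdname defaultConditions
#' @export
defaultComparisons <- function() c("AT/10A", "TG3B/AT", "CA1a/AT")

#' Simulate phosphosite spectral-count tables with planted changes
#'
#' Run-level spectral counts are drawn from a negative binomial (spectral
#' counts are overdispersed, with many exact zeros at low means). Each
#' site's expected total per condition is \code{baselineMean}, split evenly
#' over \code{nRuns} runs. A fraction of proteins is differential: each of
#' their sites is independently planted (at least one per protein) with a
#' random direction and a random target comparison, and its mean in that
#' comparison's numerator condition is multiplied (direction +1) or divided
#' (direction -1) by \code{effectFold}.
#'
#' @param nProteins number of phosphoproteins.
#' @param sitesPerProteinRange integer range of sites per protein.
#' @param conditions condition names.
#' @param comparisons comparisons in which effects may be planted.
#' @param nRuns runs per condition (default 9).
#' @param baselineMean expected total spectral count per site and condition.
#' @param dispersion negative-binomial size parameter per run.
#' @param fractionDifferential fraction of proteins with planted sites.
#' @param effectFold fold applied to planted sites (>= 1).
#' @param seed integer seed; the output is a pure function of (parameters,
#'   seed).
#' @return list with \code{counts} (run-level
#'   \linkS4class{PhosphoCountSet}) and \code{truth} (list: \code{params}
#'   and a per-site data.frame \code{sites} with \code{protein_id},
#'   \code{site_id}, \code{differential}, \code{comparison},
#'   \code{direction}).
#' @export
simulatePhosphoCounts <- function(nProteins = 200,
                                  sitesPerProteinRange = c(1, 8),
                                  conditions = defaultConditions(),
                                  comparisons = defaultComparisons(),
                                  nRuns = 9,
                                  baselineMean = 20,
                                  dispersion = 5,
                                  fractionDifferential = 0.3,
                                  effectFold = 10,
                                  seed = NULL) {
    stopifnot(fractionDifferential >= 0, fractionDifferential <= 1,
              effectFold >= 1, nRuns >= 1, baselineMean > 0, dispersion > 0)
    if (!is.null(seed)) set.seed(seed)
    prot <- sprintf("P%04d", seq_len(nProteins))
    nSites <- .sampleRange(sitesPerProteinRange[1],
                           sitesPerProteinRange[2], nProteins)
    diffProt <- sample(prot, round(fractionDifferential * nProteins))
    rows <- list()
    for (i in seq_len(nProteins)) {
        p <- prot[i]
        isDiff <- p %in% diffProt
        planted <- if (isDiff) {
            pl <- stats::runif(nSites[i]) < 0.5
            if (!any(pl)) pl[sample(nSites[i], 1)] <- TRUE
            pl
        } else rep(FALSE, nSites[i])
        rows[[i]] <- data.frame(
            protein_id = p,
            site_id = sprintf("S%d", seq_len(nSites[i]) * 10 + 1),
            differential = planted,
            comparison = ifelse(planted,
                                sample(comparisons, nSites[i],
                                       replace = TRUE), NA),
            direction = ifelse(planted,
                               sample(c(-1L, 1L), nSites[i],
                                      replace = TRUE), 0L),
            stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    ## per-site expected totals per condition
    mu <- matrix(baselineMean, nrow(truth), length(conditions),
                 dimnames = list(NULL, conditions))
    pl <- which(truth$differential)
    for (j in pl) {
        num <- parseComparison(truth$comparison[j])["numerator"]
        mu[j, num] <- if (truth$direction[j] > 0)
            mu[j, num] * effectFold else mu[j, num] / effectFold
    }
    cond <- rep(conditions, each = nRuns)
    run <- rep(sprintf("r%d", seq_len(nRuns)), times = length(conditions))
    cts <- matrix(0L, nrow(truth), length(cond))
    for (cix in seq_along(cond))
        cts[, cix] <- stats::rnbinom(nrow(truth), size = dispersion,
                                     mu = mu[, cond[cix]] / nRuns)
    params <- list(nProteins = nProteins,
                   sitesPerProteinRange = sitesPerProteinRange,
                   conditions = conditions, comparisons = comparisons,
                   nRuns = nRuns, baselineMean = baselineMean,
                   dispersion = dispersion,
                   fractionDifferential = fractionDifferential,
                   effectFold = effectFold, seed = seed)
    list(counts = PhosphoCountSet(cts, truth$protein_id, truth$site_id,
                                  condition = cond, run = run),
         truth = list(params = params, sites = truth))
}

#' Simulate a planted-partition interaction network
#'
#' A stochastic block model: node pairs within a block are connected with
#' probability \code{pIn}, pairs across blocks with \code{pOut}. The
#' default block sizes mirror a typical clustered differential-protein
#' network (ten clusters from 54 down to 3 nodes).
#'
#' @param communitySizes integer vector of block sizes.
#' @param pIn,pOut within- and between-block edge probabilities,
#'   \code{0 <= pOut < pIn <= 1}.
#' @param seed integer seed.
#' @return list with \code{network} (an \linkS4class{InteractionNetwork})
#'   and \code{truth} (list: \code{params} and data.frame \code{nodes}
#'   with \code{node_id}, \code{block}).
#' @export
simulateNetwork <- function(communitySizes = c(54, 45, 28, 28, 25,
                                               18, 11, 9, 4, 3),
                            pIn = 0.6, pOut = 0.02, seed = NULL) {
    stopifnot(pOut >= 0, pOut < pIn, pIn <= 1, all(communitySizes >= 1))
    if (!is.null(seed)) set.seed(seed)
    n <- sum(communitySizes)
    k <- length(communitySizes)
    pref <- matrix(pOut, k, k); diag(pref) <- pIn
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = communitySizes)
    ids <- sprintf("N%04d", seq_len(n))
    igraph::V(g)$name <- ids
    net <- new("InteractionNetwork", graph = igraph::simplify(g),
               clusterLabels = character())
    validObject(net)
    params <- list(communitySizes = communitySizes, pIn = pIn, pOut = pOut,
                   seed = seed)
    list(network = net,
         truth = list(params = params,
                      nodes = data.frame(
                          node_id = ids,
                          block = rep(seq_len(k), communitySizes),
                          stringsAsFactors = FALSE)))
}

#' Simulate exon-probe intensities with planted splice divergence
#'
#' Every gene gets a baseline per-probe log2 intensity shared by both
#' conditions plus independent normal replicate noise. A planted fraction
#' of genes is "spliced": in the numerator condition their probes diverge
#' downward along the gene, emulating transcripts whose 5'-most probes stay
#' concordant while 3' probes drop. The default \code{profile = "ramp"}
#' grows linearly from zero at the 5'-most probe to twice
#' \code{divergenceAmplitude} at the 3'-most probe (so the gene-averaged
#' divergence equals \code{divergenceAmplitude} log2 units);
#' \code{profile = "step"} instead shifts the 3' half of the probes by
#' twice the amplitude. \code{foldCoupling} adds a whole-gene downward
#' shift (log2 units) to spliced genes, coupling large negative signed
#' folds to high exon SD. A fraction of probes is emitted as junction
#' probes, which downstream statistics exclude.
#'
#' @param nGenes number of genes.
#' @param probesPerGeneRange integer range of probes per gene (min 5).
#' @param replicates replicates per condition (default 3).
#' @param conditions length-2 character vector: numerator, denominator.
#' @param noiseSd replicate noise SD (log2 units).
#' @param fractionSpliced fraction of genes with planted divergence.
#' @param divergenceAmplitude gene-averaged divergence, log2 units.
#' @param foldCoupling whole-gene log2 shift added to spliced genes
#'   (0 = none).
#' @param junctionFraction fraction of probes emitted as junction probes.
#' @param profile divergence shape, \code{"ramp"} or \code{"step"}.
#' @param seed integer seed.
#' @return list with \code{probes} (an \linkS4class{ExonProbeSet}) and
#'   \code{truth} (list: \code{params} and per-gene data.frame
#'   \code{genes} with \code{gene_id}, \code{spliced}, \code{n_probes},
#'   \code{amplitude}, \code{fold_shift}).
#' @export
simulateExonData <- function(nGenes = 500,
                             probesPerGeneRange = c(5, 12),
                             replicates = 3,
                             conditions = c("CA1a", "AT"),
                             noiseSd = 0.25,
                             fractionSpliced = 0.04,
                             divergenceAmplitude = 2,
                             foldCoupling = 3,
                             junctionFraction = 0.15,
                             profile = c("ramp", "step"),
                             seed = NULL) {
    profile <- match.arg(profile)
    stopifnot(probesPerGeneRange[1] >= 5, length(conditions) == 2,
              fractionSpliced >= 0, fractionSpliced <= 1,
              divergenceAmplitude >= 0, junctionFraction >= 0,
              junctionFraction < 1, replicates >= 1, noiseSd >= 0)
    if (!is.null(seed)) set.seed(seed)
    genes <- sprintf("G%04d", seq_len(nGenes))
    nProbes <- .sampleRange(probesPerGeneRange[1], probesPerGeneRange[2],
                            nGenes)
    spliced <- genes %in% sample(genes, round(fractionSpliced * nGenes))
    rows <- list()
    for (i in seq_len(nGenes)) {
        n <- nProbes[i]
        base <- stats::rnorm(1, 8, 1.5) + stats::rnorm(n, 0, 1)
        div <- rep(0, n)
        if (spliced[i]) {
            div <- if (profile == "ramp")
                -2 * divergenceAmplitude * (seq_len(n) - 1) / (n - 1)
            else
                -2 * divergenceAmplitude * (seq_len(n) > ceiling(n / 2))
            div <- div - foldCoupling
        }
        ptype <- ifelse(stats::runif(n) < junctionFraction,
                        "junction", "coding_exon")
        rows[[i]] <- data.frame(
            gene_id = genes[i],
            probe_id = sprintf("%s_p%02d", genes[i], seq_len(n)),
            probe_index = seq_len(n), probe_type = ptype,
            base = base, div = div, stringsAsFactors = FALSE)
    }
    rd <- do.call(rbind, rows)
    cond <- rep(conditions, each = replicates)
    repl <- rep(sprintf("rep%d", seq_len(replicates)), 2)
    ints <- matrix(0, nrow(rd), length(cond))
    for (cix in seq_along(cond)) {
        eff <- if (cond[cix] == conditions[1]) rd$div else 0
        ints[, cix] <- rd$base + eff + stats::rnorm(nrow(rd), 0, noiseSd)
    }
    params <- list(nGenes = nGenes, probesPerGeneRange = probesPerGeneRange,
                   replicates = replicates, conditions = conditions,
                   noiseSd = noiseSd, fractionSpliced = fractionSpliced,
                   divergenceAmplitude = divergenceAmplitude,
                   foldCoupling = foldCoupling,
                   junctionFraction = junctionFraction,
                   profile = profile, seed = seed)
    list(probes = ExonProbeSet(ints, genes = rd$gene_id,
                               probes = rd$probe_id,
                               probeIndex = rd$probe_index,
                               probeType = rd$probe_type,
                               condition = cond, replicate = repl),
         truth = list(params = params,
                      genes = data.frame(
                          gene_id = genes, spliced = spliced,
                          n_probes = nProbes,
                          amplitude = ifelse(spliced,
                                             divergenceAmplitude, 0),
                          fold_shift = ifelse(spliced, -foldCoupling, 0),
                          stringsAsFactors = FALSE)))
}

#' Simulate annotation gene sets with one planted enriched term
#'
#' Random terms draw members uniformly from the gene universe. When
#' \code{plantedTermIn} is given, an extra term \code{"T0000"} draws at
#' least \code{plantedPurity} of its members from that subset, so that a
#' downstream selection of the subset should rank it first.
#'
#' @param genes gene universe.
#' @param nTerms number of random terms.
#' @param termSizeRange integer range of term sizes.
#' @param plantedTermIn optional gene subset seeding the planted term.
#' @param plantedPurity fraction of planted-term members drawn from the
#'   subset (default 0.9).
#' @param seed integer seed.
#' @return list with \code{annotations} (an \linkS4class{AnnotationMap})
#'   and \code{truth} (list: \code{params}, \code{planted_term} id or
#'   \code{NA}).
#' @export
simulateAnnotations <- function(genes, nTerms = 50,
                                termSizeRange = c(10, 100),
                                plantedTermIn = NULL,
                                plantedPurity = 0.9, seed = NULL) {
    stopifnot(all(plantedTermIn %in% genes), nTerms >= 0,
              plantedPurity > 0, plantedPurity <= 1)
    if (!is.null(seed)) set.seed(seed)
    sizes <- if (nTerms)
        .sampleRange(termSizeRange[1], min(termSizeRange[2], length(genes)),
                     nTerms) else integer()
    sets <- lapply(sizes, function(s) sample(genes, s))
    names(sets) <- sprintf("T%04d", seq_len(nTerms))
    planted <- NA_character_
    if (!is.null(plantedTermIn) && length(plantedTermIn)) {
        s <- min(length(plantedTermIn),
                 max(termSizeRange[1], min(termSizeRange[2],
                                           length(plantedTermIn))))
        nIn <- ceiling(plantedPurity * s)
        members <- sample(plantedTermIn, nIn)
        pool <- setdiff(genes, plantedTermIn)
        if (s - nIn > 0 && length(pool))
            members <- c(members, sample(pool, min(s - nIn, length(pool))))
        planted <- "T0000"
        sets <- c(stats::setNames(list(members), planted), sets)
    }
    nms <- stats::setNames(sprintf("simulated term %s", names(sets)),
                           names(sets))
    if (!is.na(planted)) nms[planted] <- "planted enriched term"
    params <- list(nTerms = nTerms, termSizeRange = termSizeRange,
                   plantedPurity = plantedPurity, seed = seed)
    list(annotations = AnnotationMap(sets, nms),
         truth = list(params = params, planted_term = planted))
}

#' Write a simulated dataset with its ground truth
#'
#' Serializes a generator result into \code{dir}: the dataset in its
#' on-disk exchange format (count/probe TSV, SIF or GMT), every truth
#' table as \code{<prefix>_truth_<name>.tsv}, and the full parameter set
#' (including the seed) as \code{<prefix>_params.yaml}, so the dataset can
#' be regenerated bit-identically.
#'
#' @param sim a result list from one of the \code{simulate*} functions.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    seed <- sim$truth$params$seed
    paths <- character()
    dataName <- setdiff(names(sim), "truth")[1]
    obj <- sim[[dataName]]
    dataPath <- file.path(dir, paste0(prefix, "_", dataName,
        if (is(obj, "InteractionNetwork")) ".sif"
        else if (is(obj, "AnnotationMap")) ".gmt" else ".tsv"))
    if (is(obj, "PhosphoCountSet")) writePhosphoCounts(obj, dataPath, seed)
    else if (is(obj, "ExonProbeSet")) writeExonProbes(obj, dataPath, seed)
    else if (is(obj, "InteractionNetwork")) writeNetwork(obj, dataPath, seed)
    else if (is(obj, "AnnotationMap")) writeGmt(obj, dataPath, seed)
    else stop("unrecognized dataset class: ", class(obj)[1])
    paths <- c(paths, dataPath)
    for (nm in names(sim$truth)) {
        if (!is.data.frame(sim$truth[[nm]])) next
        p <- file.path(dir, paste0(prefix, "_truth_", nm, ".tsv"))
        .writeTsv(sim$truth[[nm]], p, seed)
        paths <- c(paths, p)
    }
    yp <- file.path(dir, paste0(prefix, "_params.yaml"))
    yaml::write_yaml(sim$truth$params, yp)
    invisible(c(paths, yp))
}
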