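#' Per-probe mean log2 intensity differences for one gene
#'
#' For every coding exon probe of a gene (junction probes are excluded),
#' the delta is the mean log2 intensity over replicates in the numerator
#' condition minus the mean in the denominator condition, returned in
#' 5'-to-3' probe order.
#'
#' @param x an \linkS4class{ExonProbeSet}.
#' @param geneId gene identifier present in \code{x}.
#' @param comparison comparison string \code{"numerator/denominator"}.
#' @param minProbes minimum coding probes required (default 3); genes below
#'   it are skipped with a message, returning \code{NULL}.
#' @return numeric delta vector named by probe id, or \code{NULL} when the
#'   gene has too few coding probes.
#' @export
probeDeltas <- function(x, geneId, comparison, minProbes = 3) {
    stopifnot(is(x, "ExonProbeSet"))
    cmp <- parseComparison(comparison)
    rd <- rowData(x)
    sel <- which(rd$gene_id == geneId & rd$probe_type == "coding_exon")
    if (!length(which(rd$gene_id == geneId)))
        stop("gene '", geneId, "' not found")
    if (length(sel) < minProbes) {
        message("gene ", geneId, " skipped: ", length(sel),
                " coding probe(s) < ", minProbes)
        return(NULL)
    }
    sel <- sel[order(rd$probe_index[sel])]
    cond <- as.character(colData(x)$condition)
    if (!all(cmp %in% cond))
        stop("unknown condition(s) in comparison '", comparison, "'")
    ints <- assay(x, "log2intensity")
    numMean <- rowMeans(ints[sel, cond == cmp["numerator"], drop = FALSE])
    denMean <- rowMeans(ints[sel, cond == cmp["denominator"], drop = FALSE])
    stats::setNames(numMean - denMean, rd$probe_id[sel])
}

#' Exon-probe SD: the splice-variation statistic
#'
#' The sample standard deviation (n - 1 denominator) of a gene's per-probe
#' log2 intensity deltas between two conditions. A uniform expression shift
#' moves every probe equally and gives SD 0; probe-level heterogeneity --
#' the signature of differential exon usage -- inflates it.
#'
#' @param deltas numeric vector of per-probe deltas, length >= 3.
#' @return non-negative numeric SD.
#' @examples
#' spliceSD(c(0, 0, 3))      # 1.732
#' spliceSD(rep(2.5, 4))     # 0: pure expression shift
#' @export
spliceSD <- function(deltas) {
    if (length(deltas) < 3L)
        stop("splice SD requires at least 3 probe deltas")
    stats::sd(deltas)
}

#' Per-gene splice variation for one comparison
#'
#' Computes, for every gene with at least \code{minProbes} coding exon
#' probes, the probe deltas, their sample SD, the mean delta and the signed
#' fold change \code{\link{signedFold}(mean delta)}. Genes with fewer
#' coding probes are skipped and reported in a message.
#'
#' @param x an \linkS4class{ExonProbeSet}.
#' @param comparison comparison string \code{"numerator/denominator"}.
#' @param minProbes minimum coding probes per gene (default 3).
#' @return data.frame with columns \code{gene_id}, \code{comparison},
#'   \code{n_probes}, \code{sd}, \code{mean_delta}, \code{signed_fold}.
#' @export
spliceVariation <- function(x, comparison, minProbes = 3) {
    stopifnot(is(x, "ExonProbeSet"))
    cmp <- parseComparison(comparison)
    rd <- rowData(x)
    cond <- as.character(colData(x)$condition)
    if (!all(cmp %in% cond))
        stop("unknown condition(s) in comparison '", comparison, "'")
    ints <- assay(x, "log2intensity")
    numMean <- rowMeans(ints[, cond == cmp["numerator"], drop = FALSE])
    denMean <- rowMeans(ints[, cond == cmp["denominator"], drop = FALSE])
    delta <- numMean - denMean
    coding <- rd$probe_type == "coding_exon"
    bygene <- split(seq_len(nrow(rd))[coding], rd$gene_id[coding])
    nshort <- sum(!unique(rd$gene_id) %in%
                  names(bygene)[lengths(bygene) >= minProbes])
    if (nshort)
        message(nshort, " gene(s) skipped: fewer than ", minProbes,
                " coding probes")
    bygene <- bygene[lengths(bygene) >= minProbes]
    out <- lapply(names(bygene), function(g) {
        idx <- bygene[[g]][order(rd$probe_index[bygene[[g]]])]
        d <- delta[idx]
        m <- mean(d)
        data.frame(gene_id = g, comparison = comparison,
                   n_probes = length(d), sd = stats::sd(d),
                   mean_delta = m, signed_fold = signedFold(m),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Summarize signed fold changes by exon-SD bin
#'
#' Genes are binned by their exon-probe SD into [0,1), [1,2) and [2, Inf);
#' each bin reports the mean and SD of the signed fold changes and the
#' percentage of genes it holds (percentages sum to 100).
#'
#' @param genes data.frame from \code{\link{spliceVariation}}.
#' @param breaks increasing bin edges (default \code{c(0, 1, 2, Inf)}).
#' @return data.frame with \code{bin}, \code{n_genes}, \code{percent},
#'   \code{mean_signed_fold}, \code{sd_signed_fold}; zero rows on empty
#'   input.
#' @export
binBySd <- function(genes, breaks = c(0, 1, 2, Inf)) {
    labs <- paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")")
    labs[length(labs)] <- paste0(">=", breaks[length(breaks) - 1])
    if (is.null(genes) || !nrow(genes))
        return(data.frame(bin = character(), n_genes = integer(),
                          percent = numeric(), mean_signed_fold = numeric(),
                          sd_signed_fold = numeric()))
    bin <- cut(genes$sd, breaks, labels = labs, right = FALSE,
               include.lowest = FALSE)
    out <- do.call(rbind, lapply(labs, function(b) {
        f <- genes$signed_fold[which(bin == b)]
        data.frame(bin = b, n_genes = length(f),
                   percent = 100 * length(f) / nrow(genes),
                   mean_signed_fold = if (length(f)) mean(f) else NA_real_,
                   sd_signed_fold = if (length(f) > 1) stats::sd(f)
                                    else NA_real_,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Compare two exon-SD distributions by Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test between the SD values of two pairwise
#' comparisons, by default restricted to genes with SD >= 1 (the population
#' in which splice variation is visible). The exact distribution is used
#' for small tie-free samples, the normal approximation with tie correction
#' otherwise.
#'
#' @param sds1,sds2 numeric vectors of per-gene SD values.
#' @param restrictMinSd keep only values >= this (default 1); set 0 to
#'   compare all genes.
#' @return list with \code{p} (two-sided p-value), \code{W} (rank-sum
#'   statistic) and \code{n1}, \code{n2} after restriction.
#' @export
compareSdDistributions <- function(sds1, sds2, restrictMinSd = 1) {
    a <- sds1[sds1 >= restrictMinSd]
    b <- sds2[sds2 >= restrictMinSd]
    if (!length(a) || !length(b))
        stop("no values remain after restricting to SD >= ", restrictMinSd)
    ## ties are expected among SD values; the tie-corrected normal
    ## approximation is then used, so the exactness warning is redundant
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided"))
    list(p = wt$p.value, W = unname(wt$statistic),
         n1 = length(a), n2 = length(b))
}

#' High-SD enrichment among the top fold-changed genes
#'
#' Ranks genes by |signed fold| (ties broken by gene id), takes the top
#' \code{topN}, and asks whether genes with exon SD >= \code{sdCut} are
#' over-represented there relative to the whole cohort, using the one-sided
#' hypergeometric upper tail.
#'
#' @param genes data.frame from \code{\link{spliceVariation}}.
#' @param topN number of top genes (default 100).
#' @param sdCut SD threshold defining "high splice variation" (default 1).
#' @return list with \code{proportion} (of top genes with SD >= sdCut),
#'   \code{p}, and the hypergeometric parameters \code{k}, \code{K},
#'   \code{n}, \code{N}.
#' @export
topFoldEnrichment <- function(genes, topN = 100, sdCut = 1) {
    if (length(topN) != 1L || topN <= 0)
        stop("topN must be a positive integer")
    if (nrow(genes) < topN)
        stop("need at least topN = ", topN, " genes, have ", nrow(genes))
    ord <- order(-abs(genes$signed_fold), genes$gene_id)
    top <- genes[ord[seq_len(topN)], ]
    k <- sum(top$sd >= sdCut)
    K <- sum(genes$sd >= sdCut)
    N <- nrow(genes)
    p <- stats::phyper(k - 1, K, N - K, topN, lower.tail = FALSE)
    list(proportion = k / topN, p = p,
         k = k, K = K, n = as.integer(topN), N = N)
}

#' Positional probe profile along genes
#'
#' Summarizes where along the mRNA the expression difference lies for a set
#' of genes: per gene, the 5'-most probe forms group 1, the 3'-most probe
#' the last group, and the remaining probes are split 5' to 3' into
#' \code{nMiddleGroups} contiguous, near-equal runs (earlier runs take the
#' remainder). Group values are per-gene mean deltas; the profile reports
#' each group's mean and SD across genes and a one-way ANOVA of group
#' values (gene as the replication unit).
#'
#' @param x an \linkS4class{ExonProbeSet}.
#' @param geneIds genes to profile; genes with fewer than
#'   \code{nMiddleGroups + 2} coding probes are skipped with a message.
#' @param comparison comparison string \code{"numerator/denominator"}.
#' @param nMiddleGroups number of interior groups (default 3, i.e. middle
#'   probes grouped into thirds).
#' @return list with \code{profile} (data.frame: \code{group},
#'   \code{mean}, \code{sd}, \code{n_genes}), \code{perGene} (gene x group
#'   matrix of group means), and \code{anova} (list with \code{F},
#'   \code{p}, \code{df1}, \code{df2}).
#' @export
positionalProfile <- function(x, geneIds, comparison, nMiddleGroups = 3) {
    stopifnot(nMiddleGroups >= 1)
    nGroups <- nMiddleGroups + 2L
    rows <- list()
    for (g in geneIds) {
        d <- suppressMessages(
            probeDeltas(x, g, comparison, minProbes = nGroups))
        if (is.null(d)) {
            message("gene ", g, " skipped: fewer than ", nGroups,
                    " coding probes")
            next
        }
        rows[[g]] <- vapply(split(d, .positionGroups(length(d),
                                                     nMiddleGroups)),
                            mean, numeric(1))
    }
    if (!length(rows))
        stop("no gene has enough coding probes for ", nGroups, " groups")
    perGene <- do.call(rbind, rows)
    colnames(perGene) <- seq_len(nGroups)
    profile <- data.frame(group = seq_len(nGroups),
                          mean = colMeans(perGene),
                          sd = apply(perGene, 2, stats::sd),
                          n_genes = nrow(perGene), row.names = NULL)
    long <- data.frame(value = as.vector(perGene),
                       group = factor(rep(seq_len(nGroups),
                                          each = nrow(perGene))))
    an <- stats::anova(stats::aov(value ~ group, data = long))
    list(profile = profile, perGene = perGene,
         anova = list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                      df1 = an[["Df"]][1], df2 = an[["Df"]][2]))
}

## assign probe positions 1..n to groups: first probe, nMiddle contiguous
## near-equal interior runs (earlier runs take the remainder), last probe
.positionGroups <- function(n, nMiddle) {
    stopifnot(n >= nMiddle + 2)
    m <- n - 2L
    base <- m %/% nMiddle
    extra <- m %% nMiddle
    sizes <- rep(base, nMiddle) + c(rep(1L, extra),
                                    rep(0L, nMiddle - extra))
    c(1L, rep(seq_len(nMiddle) + 1L, times = sizes), nMiddle + 2L)
}
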