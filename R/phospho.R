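#' Sum run-level spectral counts into per-condition totals
#'
#' Spectral counts from replicate LC-MS/MS runs of the same cell line are
#' summed into a single column per condition. Idempotent on tables that are
#' already aggregated.
#'
#' @param x a \linkS4class{PhosphoCountSet}.
#' @return a \linkS4class{PhosphoCountSet} with one column per condition
#'   (\code{run} set to \code{NA}).
#' @export
aggregateRuns <- function(x) {
    stopifnot(is(x, "PhosphoCountSet"))
    cond <- as.character(colData(x)$condition)
    ucond <- unique(cond)
    cts <- assay(x, "counts")
    agg <- vapply(ucond, function(co)
        as.integer(rowSums(cts[, cond == co, drop = FALSE])),
        integer(nrow(cts)))
    agg <- matrix(agg, nrow = nrow(cts), dimnames = list(NULL, ucond))
    PhosphoCountSet(agg, proteins = rowData(x)$protein_id,
                    sites = rowData(x)$site_id, condition = ucond)
}

#' Spectral-count ratio with a symmetric pseudocount
#'
#' Ratio of numerator over denominator condition counts after adding the
#' same pseudocount to both, so that sites observed in only one condition
#' yield a finite, large (or small) ratio and sites observed in neither
#' yield exactly 1 (no evidence of change).
#'
#' @param countNum,countDen non-negative integer spectral counts
#'   (vectorized).
#' @param pseudocount positive value added to both counts; must be > 0
#'   whenever either count can be zero.
#' @return positive numeric ratio(s).
#' @examples
#' siteRatio(12, 0)   # 25: a 0 -> 12 change is a strong increase
#' siteRatio(0, 0)    # 1: absence of evidence
#' @export
siteRatio <- function(countNum, countDen, pseudocount = 0.5) {
    stopifnot(all(countNum >= 0), all(countDen >= 0))
    if (pseudocount <= 0 && any(countNum == 0 | countDen == 0))
        stop("pseudocount must be > 0 when counts can be zero")
    (countNum + pseudocount) / (countDen + pseudocount)
}

#' Score a site ratio at a fold threshold
#'
#' A phosphosite change qualifies when the spectral-count ratio between two
#' cell lines reaches the fold threshold: +1 for a >= threshold-fold
#' increase, -1 for a >= threshold-fold decrease (ratio <= 1/threshold),
#' 0 otherwise. Comparisons are inclusive and symmetric:
#' \code{scoreSite(1/r) == -scoreSite(r)}.
#'
#' @param ratio positive numeric ratio(s) from \code{\link{siteRatio}}.
#' @param foldThreshold fold-change threshold, >= 1 (default 3).
#' @return integer score(s) in \{-1, 0, +1\}.
#' @examples
#' scoreSite(c(3, 1, 0.2))  # +1, 0, -1
#' @export
scoreSite <- function(ratio, foldThreshold = 3) {
    if (!is.numeric(foldThreshold) || length(foldThreshold) != 1L ||
        foldThreshold < 1)
        stop("foldThreshold must be a single value >= 1")
    stopifnot(all(ratio > 0))
    ifelse(ratio >= foldThreshold, 1L,
           ifelse(ratio <= 1 / foldThreshold, -1L, 0L))
}

#' Qualifying phosphosite changes for one pairwise comparison
#'
#' Computes, for every phosphosite, the pseudocount ratio of aggregated
#' spectral counts between the two conditions of a comparison and its
#' -1/0/+1 score at the fold threshold.
#'
#' @param x a \linkS4class{PhosphoCountSet}; run-level tables are
#'   aggregated first.
#' @param comparison comparison string \code{"numerator/denominator"},
#'   e.g. \code{"CA1a/AT"}.
#' @param foldThreshold fold-change threshold (default 3).
#' @param pseudocount symmetric pseudocount (default 0.5).
#' @return data.frame with columns \code{protein_id}, \code{site_id},
#'   \code{comparison}, \code{count_num}, \code{count_den}, \code{ratio},
#'   \code{score}.
#' @export
siteChanges <- function(x, comparison, foldThreshold = 3, pseudocount = 0.5) {
    stopifnot(is(x, "PhosphoCountSet"))
    x <- aggregateRuns(x)
    cmp <- parseComparison(comparison)
    cond <- as.character(colData(x)$condition)
    if (!all(cmp %in% cond))
        stop("unknown condition(s) in comparison '", comparison, "': ",
             paste(setdiff(cmp, cond), collapse = ", "))
    cts <- assay(x, "counts")
    num <- cts[, match(cmp["numerator"], cond)]
    den <- cts[, match(cmp["denominator"], cond)]
    ratio <- siteRatio(num, den, pseudocount)
    data.frame(protein_id = as.character(rowData(x)$protein_id),
               site_id = as.character(rowData(x)$site_id),
               comparison = comparison,
               count_num = num, count_den = den,
               ratio = ratio,
               score = scoreSite(ratio, foldThreshold),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Net phosphorylation score from site scores
#'
#' Sums the -1/+1 qualifying site changes of one protein: the net score is
#' (sites up) - (sites down) and \code{n_qualifying} counts the sites with
#' a nonzero score.
#'
#' @param siteScores integer vector of site scores in \{-1, 0, +1\}.
#' @return list with \code{net}, \code{n_qualifying}, \code{n_plus},
#'   \code{n_minus}.
#' @examples
#' netProteinScore(c(1, 1, 1, 1, -1, -1))  # net +2 over 6 qualifying sites
#' @export
netProteinScore <- function(siteScores) {
    siteScores <- as.integer(siteScores)
    stopifnot(all(siteScores %in% c(-1L, 0L, 1L)))
    list(net = sum(siteScores),
         n_qualifying = sum(siteScores != 0L),
         n_plus = sum(siteScores == 1L),
         n_minus = sum(siteScores == -1L))
}

#' Per-protein net phosphorylation scores for one or more comparisons
#'
#' @param x a \linkS4class{PhosphoCountSet}.
#' @param comparisons character vector of \code{"num/den"} comparisons.
#' @param foldThreshold,pseudocount passed to \code{\link{siteChanges}}.
#' @return data.frame with one row per (protein, comparison):
#'   \code{protein_id}, \code{comparison}, \code{net}, \code{n_qualifying},
#'   \code{n_plus}, \code{n_minus}.
#' @export
proteinNetScores <- function(x, comparisons, foldThreshold = 3,
                             pseudocount = 0.5) {
    x <- aggregateRuns(x)
    out <- lapply(comparisons, function(cmp) {
        ch <- siteChanges(x, cmp, foldThreshold, pseudocount)
        agg <- do.call(rbind, lapply(split(ch, ch$protein_id), function(d) {
            s <- netProteinScore(d$score)
            data.frame(protein_id = d$protein_id[1], comparison = cmp,
                       net = s$net, n_qualifying = s$n_qualifying,
                       n_plus = s$n_plus, n_minus = s$n_minus,
                       stringsAsFactors = FALSE)
        }))
        agg
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Select proteins with at least one qualifying site change
#'
#' A protein is differential when at least one of its phosphosites passes
#' the fold threshold (in either direction) in at least one of the listed
#' comparisons.
#'
#' @inheritParams proteinNetScores
#' @return character vector of differential protein identifiers (sorted).
#' @export
selectDifferentialProteins <- function(x, comparisons, foldThreshold = 3,
                                       pseudocount = 0.5) {
    x <- aggregateRuns(x)
    hits <- lapply(comparisons, function(cmp) {
        ch <- siteChanges(x, cmp, foldThreshold, pseudocount)
        unique(ch$protein_id[ch$score != 0L])
    })
    sort(unique(unlist(hits)))
}

#' Summarize net phosphorylation over an interaction-network cluster
#'
#' Produces the three per-cluster statistics used to profile how
#' phosphorylation of a cluster shifts between cell lines:
#' \code{a} = sum of member net scores, \code{b} = phosphosite changes per
#' node (a / number of nodes, displayed to 2 decimals) and \code{c} = the
#' percentage of cluster nodes with at least one qualifying change
#' (displayed to 1 decimal). Cluster nodes without any qualifying change
#' contribute zero and need not be listed in \code{scores}.
#'
#' @param scores data.frame of member scores with columns \code{net} and
#'   \code{n_qualifying} (see \code{\link{proteinNetScores}}); may have
#'   zero rows.
#' @param nNodes total number of nodes in the cluster (>= number of scored
#'   members).
#' @return list with \code{a}, \code{b}, \code{c} (displayed rounding),
#'   \code{b_raw}, \code{c_raw} (unrounded) and \code{n_nodes}.
#' @examples
#' m <- data.frame(net = c(rep(1, 17), rep(-1, 3), 0),
#'                 n_qualifying = c(rep(1, 20), 1))
#' summarizeCluster(m, nNodes = 28)  # a=14, b=0.50, c=75.0
#' @export
summarizeCluster <- function(scores, nNodes) {
    if (length(nNodes) != 1L || nNodes < 1)
        stop("nNodes must be a positive integer")
    if (is.null(scores) || !nrow(scores)) {
        scores <- data.frame(net = integer(), n_qualifying = integer())
    }
    if (nrow(scores) > nNodes)
        stop("more scored members (", nrow(scores), ") than cluster nodes (",
             nNodes, ")")
    a <- sum(scores$net)
    braw <- a / nNodes
    craw <- 100 * sum(scores$n_qualifying >= 1) / nNodes
    list(a = a, b = round(braw, 2), c = round(craw, 1),
         b_raw = braw, c_raw = craw, n_nodes = as.integer(nNodes))
}

#' Cluster summaries for every cluster and comparison
#'
#' Joins per-protein net scores onto a network's cluster labels and calls
#' \code{\link{summarizeCluster}} for each (cluster, comparison) pair. The
#' denominator of each cluster is its full node count, held fixed across
#' comparisons.
#'
#' @param scores data.frame from \code{\link{proteinNetScores}} (any number
#'   of comparisons).
#' @param network an \linkS4class{InteractionNetwork} with cluster labels
#'   (see \code{\link{clusterNetwork}}).
#' @return data.frame with one row per (cluster, comparison):
#'   \code{cluster_id}, \code{comparison}, \code{n_nodes}, \code{a},
#'   \code{b}, \code{c}, \code{b_raw}, \code{c_raw}.
#' @export
clusterSummaries <- function(scores, network) {
    lab <- clusterLabels(network)
    lab <- lab[!is.na(lab)]
    out <- list()
    for (cl in sort(unique(lab))) {
        members <- names(lab)[lab == cl]
        for (cmp in unique(scores$comparison)) {
            sc <- scores[scores$comparison == cmp &
                         scores$protein_id %in% members, , drop = FALSE]
            s <- summarizeCluster(sc, nNodes = length(members))
            out[[length(out) + 1L]] <- data.frame(
                cluster_id = cl, comparison = cmp,
                n_nodes = s$n_nodes, a = s$a, b = s$b, c = s$c,
                b_raw = s$b_raw, c_raw = s$c_raw,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
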