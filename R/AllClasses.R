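#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Phosphosite spectral-count container
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{counts} assay of
#' phosphosite spectral counts. Rows are phosphosites, keyed by
#' \code{protein_id} (accession) and \code{site_id} (residue letter plus
#' 1-based position, e.g. \code{"S239"}) in \code{rowData}. Columns are
#' mass-spectrometry runs or, after \code{\link{aggregateRuns}}, whole
#' conditions, keyed by \code{condition} and \code{run} in \code{colData}
#' (aggregated tables use \code{run = NA}).
#'
#' Validity requires all counts to be non-negative integers, unique
#' (protein, site) row keys, unique (condition, run) column keys, and at
#' least one run per condition.
#'
#' @seealso \code{\link{readPhosphoCounts}}, \code{\link{aggregateRuns}},
#'   \code{\link{siteChanges}}
#' @export
setClass("PhosphoCountSet", contains = "SummarizedExperiment")

setValidity("PhosphoCountSet", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    cts <- assay(object, "counts")
    if (anyNA(cts))
        msg <- c(msg, "counts contain NA")
    bad <- which(cts < 0 | abs(cts - round(cts)) > 1e-8)
    if (length(bad))
        msg <- c(msg, sprintf("negative or non-integer count at row %d",
                              ((bad[1] - 1) %% nrow(cts)) + 1))
    rd <- rowData(object)
    if (!all(c("protein_id", "site_id") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain protein_id and site_id")
    else if (anyDuplicated(paste(rd$protein_id, rd$site_id)))
        msg <- c(msg, "duplicate (protein_id, site_id) rows")
    cd <- colData(object)
    if (!all(c("condition", "run") %in% colnames(cd)))
        msg <- c(msg, "colData must contain condition and run")
    else if (anyDuplicated(paste(cd$condition, cd$run)))
        msg <- c(msg, "duplicate (condition, run) columns")
    if (length(msg)) msg else TRUE
})

#' Exon-probe log2 intensity container
#'
#' A \linkS4class{SummarizedExperiment} with one \code{log2intensity} assay.
#' Rows are microarray probes ordered along each gene: \code{rowData} carries
#' \code{gene_id}, \code{probe_id}, \code{probe_index} (1 = 5'-most probe,
#' contiguous within each gene) and \code{probe_type}, either
#' \code{"coding_exon"} or \code{"junction"}. Junction probes are retained in
#' the container but excluded from the splice-variation statistic. Columns
#' are (condition, replicate) pairs in \code{colData}, so every probe
#' automatically has every replicate of every condition.
#'
#' @seealso \code{\link{readExonProbes}}, \code{\link{spliceVariation}}
#' @export
setClass("ExonProbeSet", contains = "SummarizedExperiment")

setValidity("ExonProbeSet", function(object) {
    msg <- character()
    if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2intensity' is missing")
    if (anyNA(assay(object, "log2intensity")))
        msg <- c(msg, "intensities contain NA")
    rd <- rowData(object)
    need <- c("gene_id", "probe_id", "probe_index", "probe_type")
    if (!all(need %in% colnames(rd)))
        return(paste("rowData must contain", paste(need, collapse = ", ")))
    if (!all(rd$probe_type %in% c("coding_exon", "junction")))
        msg <- c(msg, "probe_type must be 'coding_exon' or 'junction'")
    idx <- split(as.integer(rd$probe_index), rd$gene_id)
    for (g in names(idx)) {
        v <- sort(idx[[g]])
        if (anyDuplicated(v) || !identical(v, seq_along(v)))
            msg <- c(msg, sprintf(
                "gene %s: probe_index not unique and contiguous from 1", g))
    }
    cd <- colData(object)
    if (!all(c("condition", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain condition and replicate")
    else if (anyDuplicated(paste(cd$condition, cd$replicate)))
        msg <- c(msg, "duplicate (condition, replicate) columns")
    if (length(msg)) msg else TRUE
})

#' Undirected protein interaction network
#'
#' Wraps a simple undirected \pkg{igraph} graph over protein/gene
#' identifiers, with an optional per-node cluster label (\code{NA} =
#' unclustered). Self-loops and duplicate or reversed edges are not allowed.
#'
#' @slot graph an undirected simple \pkg{igraph} graph with named vertices.
#' @slot clusterLabels named character vector of cluster labels (possibly
#'   all \code{NA}), one per node, or length zero before clustering.
#'
#' @seealso \code{\link{readNetwork}}, \code{\link{clusterNetwork}},
#'   \code{\link{identifyKeynodes}}
#' @export
setClass("InteractionNetwork",
         slots = c(graph = "ANY", clusterLabels = "character"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    if (!igraph::is_igraph(g))
        return("graph slot must hold an igraph object")
    msg <- character()
    if (igraph::is_directed(g))
        msg <- c(msg, "graph must be undirected")
    if (!igraph::is_simple(g))
        msg <- c(msg, "graph must be simple (no loops or multi-edges)")
    if (is.null(igraph::V(g)$name))
        msg <- c(msg, "vertices must be named")
    lab <- object@clusterLabels
    if (length(lab) && !setequal(names(lab), igraph::V(g)$name))
        msg <- c(msg, "clusterLabels names must match the node set")
    if (length(msg)) msg else TRUE
})

#' Gene-set annotation map
#'
#' Term-to-gene annotation sets as read from a GMT file: a named list of
#' non-empty, duplicate-free member vectors plus a display name per term.
#'
#' @slot sets named list of character vectors (term id -> member genes).
#' @slot termNames character vector of term descriptions, named by term id.
#'
#' @seealso \code{\link{readGmt}}, \code{\link{enrichTerms}}
#' @export
setClass("AnnotationMap", slots = c(sets = "list", termNames = "character"))

setValidity("AnnotationMap", function(object) {
    msg <- character()
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || anyDuplicated(names(s)))
            msg <- c(msg, "term ids must be unique and non-empty")
        if (any(lengths(s) == 0))
            msg <- c(msg, "member sets must be non-empty")
        if (any(vapply(s, anyDuplicated, 0L) > 0))
            msg <- c(msg, "member sets must not contain duplicates")
    }
    if (!setequal(names(object@termNames), names(s)))
        msg <- c(msg, "termNames must be named by the same term ids as sets")
    if (length(msg)) msg else TRUE
})
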