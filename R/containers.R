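#' Construct a PhosphoCountSet
#'
#' @param counts numeric matrix of spectral counts, sites in rows, runs (or
#'   conditions) in columns.
#' @param proteins,sites character vectors of row keys, one per row.
#' @param condition character vector of column conditions, one per column.
#' @param run character vector of run labels (or \code{NA} for
#'   condition-level columns).
#' @return a \linkS4class{PhosphoCountSet}.
#' @examples
#' cts <- matrix(c(0, 12, 1, 13), 1, dimnames = list("EGFR:S1064", NULL))
#' pcs <- PhosphoCountSet(cts, proteins = "EGFR", sites = "S1064",
#'                        condition = c("10A", "AT", "TG3B", "CA1a"))
#' @export
PhosphoCountSet <- function(counts, proteins, sites, condition,
                            run = rep(NA_character_, ncol(counts))) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    cn <- ifelse(is.na(run), condition, paste(condition, run, sep = "."))
    dimnames(counts) <- list(paste(proteins, sites, sep = ":"), cn)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(protein_id = proteins, site_id = sites),
        colData = DataFrame(condition = condition, run = run, row.names = cn))
    new("PhosphoCountSet", se)
}

#' Construct an ExonProbeSet
#'
#' @param intensities numeric matrix of log2 intensities, probes in rows and
#'   (condition, replicate) pairs in columns.
#' @param genes,probes character row keys.
#' @param probeIndex integer 5'-to-3' probe rank within each gene (1-based,
#'   contiguous).
#' @param probeType \code{"coding_exon"} or \code{"junction"} per probe.
#' @param condition,replicate character column keys.
#' @return an \linkS4class{ExonProbeSet}.
#' @export
ExonProbeSet <- function(intensities, genes, probes, probeIndex, probeType,
                         condition, replicate) {
    intensities <- as.matrix(intensities)
    cn <- paste(condition, replicate, sep = ".")
    dimnames(intensities) <- list(paste(genes, probes, sep = ":"), cn)
    se <- SummarizedExperiment(
        assays = list(log2intensity = intensities),
        rowData = DataFrame(gene_id = genes, probe_id = probes,
                            probe_index = as.integer(probeIndex),
                            probe_type = probeType),
        colData = DataFrame(condition = condition, replicate = replicate,
                            row.names = cn))
    new("ExonProbeSet", se)
}

#' Construct an InteractionNetwork from an edge table
#'
#' Duplicate and reversed edges are collapsed; self-loop rows are dropped
#' with a warning. Nodes without edges can be added via \code{nodes}.
#'
#' @param edges two-column matrix or data.frame of node identifier pairs
#'   (may have zero rows).
#' @param nodes optional character vector of node identifiers to include
#'   even when isolated.
#' @return an \linkS4class{InteractionNetwork}.
#' @examples
#' net <- InteractionNetwork(data.frame(from = c("A", "B"), to = c("B", "C")))
#' nodeIds(net)
#' @export
InteractionNetwork <- function(edges = NULL, nodes = NULL) {
    if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
        em <- matrix(character(), ncol = 2)
    } else {
        em <- as.matrix(as.data.frame(edges)[, 1:2])
        mode(em) <- "character"
        loops <- em[, 1] == em[, 2]
        if (any(loops)) {
            warning(sum(loops), " self-loop edge(s) dropped")
            nodes <- c(nodes, em[loops, 1])  # endpoints stay as nodes
            em <- em[!loops, , drop = FALSE]
        }
    }
    verts <- unique(c(as.character(em), nodes))
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(verts, igraph::V(g)$name)),
                              name = setdiff(verts, igraph::V(g)$name))
    g <- igraph::simplify(g)
    new("InteractionNetwork", graph = g, clusterLabels = character())
}

#' Construct an AnnotationMap
#'
#' @param sets named list of member-gene character vectors; duplicates
#'   within a set are removed.
#' @param termNames optional character vector of term descriptions named by
#'   term id (defaults to the ids themselves).
#' @return an \linkS4class{AnnotationMap}.
#' @export
AnnotationMap <- function(sets, termNames = NULL) {
    sets <- lapply(sets, function(x) unique(as.character(x)))
    if (is.null(termNames))
        termNames <- stats::setNames(names(sets), names(sets))
    new("AnnotationMap", sets = sets, termNames = termNames[names(sets)])
}

## ---- accessors --------------------------------------------------------

#' Accessors for SpliceRewire containers
#'
#' \code{conditions} and \code{runs} return the column keys of a
#' \linkS4class{PhosphoCountSet} or \linkS4class{ExonProbeSet};
#' \code{proteinIds}/\code{siteIds}/\code{geneIds} the row keys;
#' \code{nodeIds} and \code{edgeTable} the vertex set and edge list of an
#' \linkS4class{InteractionNetwork}; \code{clusterLabels} its per-node
#' cluster assignment; \code{termIds}, \code{termNames} and \code{geneSets}
#' the content of an \linkS4class{AnnotationMap}.
#'
#' @param x a SpliceRewire container.
#' @param value replacement value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))
#' @rdname accessors
#' @export
setMethod("conditions", "SummarizedExperiment",
          function(x) unique(as.character(colData(x)$condition)))

#' @rdname accessors
#' @export
setGeneric("runs", function(x) standardGeneric("runs"))
#' @rdname accessors
#' @export
setMethod("runs", "PhosphoCountSet",
          function(x) as.character(colData(x)$run))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setMethod("proteinIds", "PhosphoCountSet",
          function(x) unique(as.character(rowData(x)$protein_id)))

#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setMethod("siteIds", "PhosphoCountSet",
          function(x) as.character(rowData(x)$site_id))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExonProbeSet",
          function(x) unique(as.character(rowData(x)$gene_id)))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setMethod("nodeIds", "InteractionNetwork",
          function(x) igraph::V(x@graph)$name)

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setMethod("edgeTable", "InteractionNetwork", function(x) {
    el <- igraph::as_edgelist(x@graph)
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))
#' @rdname accessors
#' @export
setMethod("networkGraph", "InteractionNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "InteractionNetwork", function(x) {
    if (length(x@clusterLabels)) x@clusterLabels
    else stats::setNames(rep(NA_character_, length(nodeIds(x))), nodeIds(x))
})

#' @rdname accessors
#' @export
setGeneric("clusterLabels<-",
           function(x, value) standardGeneric("clusterLabels<-"))
#' @rdname accessors
#' @export
setMethod("clusterLabels<-", "InteractionNetwork", function(x, value) {
    x@clusterLabels <- value[nodeIds(x)]
    names(x@clusterLabels) <- nodeIds(x)
    validObject(x)
    x
})

#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setMethod("termIds", "AnnotationMap", function(x) names(x@sets))

#' @rdname accessors
#' @export
setGeneric("termNames", function(x) standardGeneric("termNames"))
#' @rdname accessors
#' @export
setMethod("termNames", "AnnotationMap", function(x) x@termNames)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "AnnotationMap", function(x) x@sets)

## ---- show -------------------------------------------------------------

setMethod("show", "PhosphoCountSet", function(object) {
    cat("PhosphoCountSet:", nrow(object), "phosphosites on",
        length(proteinIds(object)), "proteins;",
        length(conditions(object)), "condition(s),",
        ncol(object), "column(s)\n")
})

setMethod("show", "ExonProbeSet", function(object) {
    rd <- rowData(object)
    cat("ExonProbeSet:", nrow(object), "probes (",
        sum(rd$probe_type == "coding_exon"), "coding_exon /",
        sum(rd$probe_type == "junction"), "junction ) on",
        length(geneIds(object)), "genes;",
        length(conditions(object)), "condition(s) x",
        length(unique(colData(object)$replicate)), "replicate(s)\n")
})

setMethod("show", "InteractionNetwork", function(object) {
    lab <- clusterLabels(object)
    cat("InteractionNetwork:", length(nodeIds(object)), "nodes,",
        igraph::ecount(object@graph), "edges;",
        if (all(is.na(lab))) "unclustered"
        else paste0(length(unique(stats::na.omit(lab))), " cluster(s)"),
        "\n")
})

setMethod("show", "AnnotationMap", function(object) {
    cat("AnnotationMap:", length(object@sets), "terms, set sizes",
        if (length(object@sets))
            paste(range(lengths(object@sets)), collapse = "-") else "-",
        "\n")
})
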