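#' Cluster a protein interaction network
#'
#' Partitions the network into communities by greedy modularity
#' maximization and keeps communities with at least \code{minClusterSize}
#' nodes; nodes in smaller communities are left unclustered (\code{NA}
#' label). Cluster ids are \code{"1"}, \code{"2"}, ... in order of
#' decreasing size. The algorithm is deterministic.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param minClusterSize minimum nodes per retained cluster (default 3).
#' @return the network with \code{\link{clusterLabels}} filled in.
#' @export
clusterNetwork <- function(network, minClusterSize = 3) {
    stopifnot(is(network, "InteractionNetwork"))
    g <- network@graph
    nodes <- igraph::V(g)$name
    if (!length(nodes)) {
        network@clusterLabels <- character()
        return(network)
    }
    memb <- igraph::membership(igraph::cluster_fast_greedy(g))
    sizes <- sort(table(memb), decreasing = TRUE)
    keep <- names(sizes)[sizes >= minClusterSize]
    lab <- rep(NA_character_, length(nodes))
    names(lab) <- nodes
    for (i in seq_along(keep))
        lab[names(memb)[memb == keep[i]]] <- as.character(i)
    clusterLabels(network) <- lab
    network
}

#' Net phosphorylation status per network node
#'
#' Maps per-protein net scores onto the categorical coloring used for
#' network rendering: negative net = \code{hypo} (hypophosphorylated),
#' zero = \code{neutral}, positive = \code{hyper}; \code{magnitude} is
#' |net| and drives shading intensity. Nodes without a score are neutral.
#'
#' @param scores data.frame with columns \code{protein_id} and \code{net}
#'   for a single comparison (see \code{\link{proteinNetScores}}).
#' @param nodes optional character vector of node ids to cover; defaults to
#'   the proteins present in \code{scores}.
#' @return data.frame with \code{node_id}, \code{net}, \code{category},
#'   \code{magnitude}.
#' @export
nodeStatus <- function(scores, nodes = NULL) {
    if (is.null(nodes)) nodes <- scores$protein_id
    net <- scores$net[match(nodes, scores$protein_id)]
    net[is.na(net)] <- 0L
    data.frame(node_id = as.character(nodes), net = as.integer(net),
               category = ifelse(net < 0, "hypo",
                                 ifelse(net > 0, "hyper", "neutral")),
               magnitude = abs(as.integer(net)),
               stringsAsFactors = FALSE)
}

#' Identify tiered keynodes among differential proteins
#'
#' Keynodes are the most interconnected proteins among the nodes with a
#' nonzero net phosphorylation status (|net| >= 1). Selection is iterative
#' within the subgraph induced by those candidate nodes: the candidate with
#' the most candidate neighbors becomes the next-tier keynode and its
#' neighbors become its partners; later tiers are chosen among candidates
#' that are neither keynodes nor partners already, while earlier keynodes
#' and partners stay in the graph, so a partner adjacent to two or more
#' keynodes is flagged as shared. Ties are broken lexicographically by node
#' identifier, making the result deterministic.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param statuses data.frame from \code{\link{nodeStatus}} covering the
#'   nodes to consider.
#' @param nTiers maximum number of tiers to extract (default 3: primary,
#'   secondary, tertiary).
#' @return data.frame with one row per keynode: \code{keynode_id},
#'   \code{tier} (integer), \code{tier_name}, \code{connection_count}, and
#'   list-columns \code{partners} and \code{shared_partners} (partners also
#'   adjacent to another selected keynode). Zero rows when no candidates
#'   exist.
#' @export
identifyKeynodes <- function(network, statuses, nTiers = 3) {
    stopifnot(is(network, "InteractionNetwork"), nTiers >= 1)
    cand <- intersect(statuses$node_id[abs(statuses$net) >= 1],
                      nodeIds(network))
    empty <- data.frame(keynode_id = character(), tier = integer(),
                        tier_name = character(),
                        connection_count = integer(),
                        stringsAsFactors = FALSE)
    empty$partners <- list(); empty$shared_partners <- list()
    if (!length(cand)) return(empty)
    sub <- igraph::induced_subgraph(network@graph, cand)
    deg <- igraph::degree(sub)
    nbr <- lapply(igraph::adjacent_vertices(sub, igraph::V(sub)),
                  function(v) sort(v$name))
    names(nbr) <- igraph::V(sub)$name
    tiers <- c("primary", "secondary", "tertiary")
    keynodes <- character(); taken <- character()
    rows <- list()
    for (t in seq_len(nTiers)) {
        eligible <- setdiff(names(deg), taken)
        if (!length(eligible)) break
        d <- deg[eligible]
        pick <- sort(names(d)[d == max(d)])[1]
        partners <- nbr[[pick]]
        keynodes <- c(keynodes, pick)
        taken <- union(taken, c(pick, partners))
        rows[[t]] <- data.frame(
            keynode_id = pick, tier = t,
            tier_name = if (t <= 3) tiers[t] else paste0("tier", t),
            connection_count = length(partners),
            stringsAsFactors = FALSE)
        rows[[t]]$partners <- list(partners)
    }
    out <- do.call(rbind, rows)
    ## partners adjacent to >= 2 selected keynodes are shared
    out$shared_partners <- lapply(out$partners, function(p)
        p[vapply(p, function(q)
            sum(keynodes %in% nbr[[q]]) >= 2L, logical(1))])
    rownames(out) <- NULL
    out
}
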