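#' Hypergeometric gene-set over-representation test
#'
#' Tests every annotation term for over-representation in a selected gene
#' set against a background universe, using the one-sided hypergeometric
#' upper tail P(X >= k) (equivalent to a one-sided Fisher's exact test on
#' the 2x2 table), with Benjamini-Hochberg correction across all tested
#' terms. Annotation sets are intersected with the background first; terms
#' with no background member are dropped.
#'
#' Significance stars follow the convention \code{*} for p <= 0.05 and
#' \code{**} for p <= 0.001.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   \code{background}).
#' @param background character vector: the tested universe.
#' @param annotations an \linkS4class{AnnotationMap}.
#' @param minTermSize,maxTermSize keep terms whose background-intersected
#'   size is within this range (defaults 1 and Inf: no filter).
#' @return data.frame sorted by p-value with columns \code{term_id},
#'   \code{term_name}, \code{k} (selected members), \code{K} (term size in
#'   background), \code{n} (selected size), \code{N} (background size),
#'   \code{p}, \code{q} (BH-adjusted), \code{stars}.
#' @examples
#' ann <- AnnotationMap(list(T1 = c("g1", "g2", "g3")))
#' enrichTerms(c("g1", "g2"), paste0("g", 1:20), ann)
#' @export
enrichTerms <- function(selected, background, annotations,
                        minTermSize = 1, maxTermSize = Inf) {
    stopifnot(is(annotations, "AnnotationMap"))
    selected <- unique(as.character(selected))
    background <- unique(as.character(background))
    extra <- setdiff(selected, background)
    if (length(extra))
        stop("selected genes not in background: ",
             paste(utils::head(extra, 5), collapse = ", "),
             if (length(extra) > 5) ", ...")
    N <- length(background)
    n <- length(selected)
    rows <- lapply(termIds(annotations), function(id) {
        members <- intersect(geneSets(annotations)[[id]], background)
        K <- length(members)
        if (K < max(1, minTermSize) || K > maxTermSize) return(NULL)
        k <- length(intersect(selected, members))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = id,
                   term_name = unname(termNames(annotations)[id]),
                   k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p = numeric(), q = numeric(),
                          stars = character()))
    out$q <- stats::p.adjust(out$p, method = "BH")
    out$stars <- ifelse(out$p <= 0.001, "**",
                        ifelse(out$p <= 0.05, "*", ""))
    out <- out[order(out$p, out$term_id), ]
    rownames(out) <- NULL
    out
}
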