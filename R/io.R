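#' Read and write phosphosite spectral-count tables
#'
#' Tab-separated tables with columns \code{protein_id}, \code{site_id} and
#' one count column per run named \code{"condition.run"} (or per condition,
#' named \code{"condition"}, for already aggregated tables). Lines starting
#' with \code{#} are header comments and are skipped. Malformed cells are
#' rejected with the offending file line number.
#'
#' @param path file path.
#' @param x a \linkS4class{PhosphoCountSet}.
#' @param seed optional seed recorded in the output header comment.
#' @return \code{readPhosphoCounts} returns a
#'   \linkS4class{PhosphoCountSet}; the writer returns \code{path}
#'   invisibly.
#' @export
readPhosphoCounts <- function(path) {
    r <- .readTsv(path)
    df <- r$data
    if (!all(c("protein_id", "site_id") %in% colnames(df)))
        stop("format error in '", path,
             "': required columns protein_id, site_id are missing")
    valcols <- setdiff(colnames(df), c("protein_id", "site_id"))
    if (!length(valcols))
        stop("format error in '", path, "': no count columns present")
    cts <- suppressWarnings(
        vapply(df[valcols], as.numeric, numeric(nrow(df))))
    cts <- matrix(cts, nrow = nrow(df),
                  dimnames = list(NULL, valcols))
    bad <- which(is.na(cts) | cts < 0 | abs(cts - round(cts)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad))
        stop("validation error in '", path, "' line ", r$lineno[bad[1, 1]],
             ": count '", df[[valcols[bad[1, 2]]]][bad[1, 1]],
             "' is not a non-negative integer")
    key <- .splitColKey(valcols)
    PhosphoCountSet(cts, proteins = df$protein_id, sites = df$site_id,
                    condition = key$condition, run = key$run)
}

#' @rdname readPhosphoCounts
#' @export
writePhosphoCounts <- function(x, path, seed = NA) {
    cd <- colData(x)
    cn <- ifelse(is.na(cd$run), as.character(cd$condition),
                 paste(cd$condition, cd$run, sep = "."))
    df <- data.frame(protein_id = rowData(x)$protein_id,
                     site_id = rowData(x)$site_id,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df[cn] <- as.data.frame(assay(x, "counts"))
    .writeTsv(df, path, seed)
}

#' Read and write exon-probe intensity tables
#'
#' Tab-separated tables with columns \code{gene_id}, \code{probe_id},
#' \code{probe_index}, \code{probe_type} and one log2 intensity column per
#' (condition, replicate) pair named \code{"condition.replicate"}. Junction
#' probes are retained (and flagged by \code{probe_type}); the
#' splice-variation statistic excludes them later. Genes whose
#' \code{probe_index} values are not unique and contiguous from 1 are
#' rejected.
#'
#' @param path file path.
#' @param x an \linkS4class{ExonProbeSet}.
#' @param seed optional seed recorded in the output header comment.
#' @return \code{readExonProbes} returns an \linkS4class{ExonProbeSet};
#'   the writer returns \code{path} invisibly.
#' @export
readExonProbes <- function(path) {
    r <- .readTsv(path)
    df <- r$data
    need <- c("gene_id", "probe_id", "probe_index", "probe_type")
    if (!all(need %in% colnames(df)))
        stop("format error in '", path, "': required columns ",
             paste(setdiff(need, colnames(df)), collapse = ", "),
             " are missing")
    valcols <- setdiff(colnames(df), need)
    if (!length(valcols))
        stop("format error in '", path, "': no intensity columns present")
    badtype <- which(!df$probe_type %in% c("coding_exon", "junction"))
    if (length(badtype))
        stop("validation error in '", path, "' line ", r$lineno[badtype[1]],
             ": unknown probe_type '", df$probe_type[badtype[1]], "'")
    pidx <- suppressWarnings(as.integer(df$probe_index))
    if (anyNA(pidx))
        stop("validation error in '", path, "' line ",
             r$lineno[which(is.na(pidx))[1]], ": probe_index is not integer")
    dup <- duplicated(paste(df$gene_id, pidx))
    if (any(dup))
        stop("validation error in '", path, "' line ", r$lineno[which(dup)[1]],
             ": duplicate (gene_id, probe_index)")
    for (g in unique(df$gene_id)) {
        v <- sort(pidx[df$gene_id == g])
        if (!identical(v, seq_along(v)))
            stop("validation error in '", path, "': gene ", g,
                 " probe_index values (", paste(v, collapse = ","),
                 ") are not contiguous from 1")
    }
    ints <- suppressWarnings(
        vapply(df[valcols], as.numeric, numeric(nrow(df))))
    ints <- matrix(ints, nrow = nrow(df), dimnames = list(NULL, valcols))
    bad <- which(is.na(ints), arr.ind = TRUE)
    if (nrow(bad))
        stop("validation error in '", path, "' line ", r$lineno[bad[1, 1]],
             ": intensity is not numeric")
    key <- .splitColKey(valcols)
    if (anyNA(key$run))
        stop("format error in '", path,
             "': intensity columns must be named 'condition.replicate'")
    ExonProbeSet(ints, genes = df$gene_id, probes = df$probe_id,
                 probeIndex = pidx, probeType = df$probe_type,
                 condition = key$condition, replicate = key$run)
}

#' @rdname readExonProbes
#' @export
writeExonProbes <- function(x, path, seed = NA) {
    cd <- colData(x)
    cn <- paste(cd$condition, cd$replicate, sep = ".")
    rd <- rowData(x)
    df <- data.frame(gene_id = rd$gene_id, probe_id = rd$probe_id,
                     probe_index = rd$probe_index,
                     probe_type = rd$probe_type,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df[cn] <- as.data.frame(assay(x, "log2intensity"))
    .writeTsv(df, path, seed)
}

#' Read and write protein interaction edge lists
#'
#' Accepts SIF (\code{"A interacts B [C ...]"}, whitespace separated) or
#' two-column tab-separated edge lists; the format is chosen by extension
#' (\code{.sif}) or by token count. Duplicate and reversed edges are
#' collapsed; self-loop rows are dropped with a warning. The writer emits
#' SIF with relation \code{interacts}.
#'
#' @param path file path.
#' @param x an \linkS4class{InteractionNetwork}.
#' @param seed optional seed recorded in the output header comment.
#' @return \code{readNetwork} returns an \linkS4class{InteractionNetwork};
#'   the writer returns \code{path} invisibly.
#' @export
readNetwork <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    sif <- grepl("\\.sif$", path, ignore.case = TRUE) ||
        any(lengths(toks) >= 3L)
    edges <- list(); singles <- character()
    for (tk in toks) {
        if (sif) {
            if (length(tk) == 1L) { singles <- c(singles, tk); next }
            if (length(tk) < 3L)
                stop("format error in '", path,
                     "': SIF line needs 'node relation node...'")
            edges[[length(edges) + 1L]] <- cbind(tk[1], tk[-(1:2)])
        } else {
            if (length(tk) < 2L) { singles <- c(singles, tk); next }
            edges[[length(edges) + 1L]] <- cbind(tk[1], tk[2])
        }
    }
    em <- do.call(rbind, edges)
    InteractionNetwork(em, nodes = singles)
}

#' @rdname readNetwork
#' @export
writeNetwork <- function(x, path, seed = NA) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.headerLine(seed), con)
    et <- edgeTable(x)
    if (nrow(et))
        writeLines(paste(et$from, "interacts", et$to, sep = "\t"), con)
    iso <- setdiff(nodeIds(x), unique(c(et$from, et$to)))
    if (length(iso)) writeLines(iso, con)
    invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated as
#' \code{term_id<TAB>description<TAB>gene1<TAB>gene2...}. Duplicate genes
#' within a term are removed; a term repeated on several lines is merged to
#' the union of its members with a warning; lines with fewer than three
#' fields are a format error.
#'
#' @param path file path.
#' @param x an \linkS4class{AnnotationMap}.
#' @param seed optional seed recorded in the output header comment.
#' @return \code{readGmt} returns an \linkS4class{AnnotationMap}; the
#'   writer returns \code{path} invisibly.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    sets <- list(); nms <- character()
    for (i in which(keep)) {
        tk <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        tk <- tk[nzchar(tk)]
        if (length(tk) < 3L)
            stop("format error in '", path, "' line ", i,
                 ": GMT lines need term, description and >=1 member")
        id <- tk[1]
        members <- unique(tk[-(1:2)])
        if (id %in% names(sets)) {
            warning("term '", id, "' repeated; members merged")
            sets[[id]] <- unique(c(sets[[id]], members))
        } else {
            sets[[id]] <- members
            nms[id] <- tk[2]
        }
    }
    AnnotationMap(sets, nms)
}

#' @rdname readGmt
#' @export
writeGmt <- function(x, path, seed = NA) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.headerLine(seed), con)
    for (id in termIds(x))
        writeLines(paste(c(id, termNames(x)[[id]], geneSets(x)[[id]]),
                         collapse = "\t"), con)
    invisible(path)
}
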