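#' Parse a pairwise comparison label
#'
#' Comparisons are always written \code{"<numerator>/<denominator>"}
#' (e.g. \code{"CA1a/AT"}): fold changes and probe deltas are taken as
#' numerator over (minus) denominator.
#'
#' @param comparison a single string of the form \code{"A/B"}.
#' @return named character vector with elements \code{numerator} and
#'   \code{denominator}.
#' @examples
#' parseComparison("CA1a/AT")
#' @export
parseComparison <- function(comparison) {
    stopifnot(is.character(comparison), length(comparison) == 1L)
    parts <- strsplit(comparison, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L || any(!nzchar(parts)))
        stop("comparison must be of the form 'numerator/denominator', got '",
             comparison, "'")
    c(numerator = parts[1], denominator = parts[2])
}

#' Signed fold change from a mean log2 difference
#'
#' Converts a mean log2 ratio \code{m} to the signed-fold convention used by
#' array analysis consoles: \code{2^m} for \code{m >= 0} and
#' \code{-2^(-m)} otherwise, so down-regulation of magnitude f is written
#' -f and no value falls strictly between -1 and 1.
#'
#' @param m numeric vector of mean log2 differences.
#' @return numeric vector of signed folds, \code{|fold| >= 1}.
#' @examples
#' signedFold(c(-3, 0, 1))  # -8, 1, 2
#' @export
signedFold <- function(m) {
    ifelse(m >= 0, 2^m, -(2^(-m)))
}

## output header comment recording tool version (and seed when known)
.headerLine <- function(seed = NA) {
    sprintf("# SpliceRewire %s seed=%s",
            as.character(utils::packageVersion("SpliceRewire")),
            as.character(seed))
}

## read a TSV, skipping leading '#' comment lines; returns the data.frame
## plus the file line number of each data row (for error messages)
.readTsv <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    body <- lines[keep]
    if (length(body) < 1L)
        stop("file '", path, "' has no header line")
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    list(data = df, lineno = which(keep)[-1])
}

.writeTsv <- function(df, path, seed = NA) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.headerLine(seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## uniform integer draw from [lo, hi]; safe when lo == hi (base sample()
## would treat a single integer as a range)
.sampleRange <- function(lo, hi, n) {
    if (lo == hi) rep(as.integer(lo), n)
    else sample(seq.int(lo, hi), n, replace = TRUE)
}

## split "condition.run" column names on the first dot
.splitColKey <- function(x) {
    has <- grepl(".", x, fixed = TRUE)
    first <- regexpr(".", x, fixed = TRUE)
    cond <- ifelse(has, substr(x, 1, first - 1), x)
    sub <- ifelse(has, substring(x, first + 1), NA_character_)
    data.frame(condition = cond, run = sub, stringsAsFactors = FALSE)
}
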