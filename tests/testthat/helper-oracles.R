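suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check: plain arithmetic, exhaustive enumeration
# and adjacency-matrix iteration only.

# textbook two-pass sample standard deviation
oracleSD <- function(x) {
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
}

# sign-carrying log-space site scoring rule
oracleScore <- function(ratio, threshold) {
    l <- log2(ratio)
    ifelse(abs(l) >= log2(threshold), sign(l), 0)
}

# one-sided hypergeometric upper tail P(X >= k) by direct enumeration of
# all admissible 2x2 tables (Fisher's exact test, over-representation side)
oracleHyperTail <- function(k, K, n, N) {
    xs <- seq(max(0, k), min(K, n))
    if (k > min(K, n)) return(0)
    sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# exact two-sided Wilcoxon rank-sum p-value by enumerating every assignment
# of ranks to the first sample (tie-free data only)
oracleWilcoxExact <- function(x, y) {
    nx <- length(x); ny <- length(y); N <- nx + ny
    stopifnot(!anyDuplicated(c(x, y)))
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    allW <- apply(utils::combn(N, nx), 2, sum) - nx * (nx + 1) / 2
    p <- if (W > nx * ny / 2) 2 * mean(allW >= W) else 2 * mean(allW <= W)
    min(1, p)
}

# Benjamini-Hochberg step-up by explicit backward scan
oracleBH <- function(p) {
    n <- length(p); o <- order(p); q <- numeric(n); running <- 1
    for (i in n:1) {
        running <- min(running, p[o[i]] * n / i)
        q[o[i]] <- running
    }
    q
}

# tiered keynode selection on a named adjacency matrix
oracleKeynodes <- function(adj, nets, nTiers = 3) {
    cand <- sort(names(nets)[abs(nets) >= 1])
    A <- adj[cand, cand, drop = FALSE]
    taken <- character(); res <- list()
    for (t in seq_len(nTiers)) {
        elig <- setdiff(cand, taken)
        if (!length(elig)) break
        deg <- rowSums(A[elig, , drop = FALSE])
        pick <- sort(elig[deg == max(deg)])[1]
        partners <- sort(cand[A[pick, ] == 1])
        res[[t]] <- list(keynode = pick, count = sum(A[pick, ]),
                         partners = partners)
        taken <- union(taken, c(pick, partners))
    }
    res
}

# adjusted Rand index from the contingency table
oracleARI <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    tot <- choose(sum(tab), 2)
    exp_ <- si * sj / tot
    (sij - exp_) / ((si + sj) / 2 - exp_)
}

# small crafted phospho count table: one column per condition
makeCountTable <- function(counts, proteins, sites,
                           conditions = colnames(counts)) {
    PhosphoCountSet(counts, proteins = proteins, sites = sites,
                    condition = conditions)
}
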