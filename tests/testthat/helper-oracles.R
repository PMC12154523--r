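# Independent oracles used across the suite. Each is a deliberately naive,
# brute-force implementation kept free of the code paths it checks.

# Benjamini-Hochberg step-up by direct evaluation of the definition:
# q(i) = min_{j >= i} (m / j) p(j) on sorted p, capped at 1.
bh_stepup_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) {
        q[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
    }
    out <- numeric(m)
    out[o] <- q
    out
}

# Upper hypergeometric tail by explicit combinatorial enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
    i <- seq(max(k, 0), min(K, n))
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Spearman rho as Pearson on hand-computed average ranks.
mean_rank <- function(x) {
    vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}
spearman_oracle <- function(x, y) {
    rx <- mean_rank(x); ry <- mean_rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Two-sided exact binomial p by brute-force tail summation: outcomes whose
# point probability does not exceed the observed one.
binom_two_sided_oracle <- function(x, n, p) {
    d <- dbinom(0:n, n, p)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Sliding-window trimming by exhaustive window scan.
trim_oracle <- function(qual, window, minq, offset = 33) {
    q <- utf8ToInt(qual) - offset
    L <- length(q)
    if (L < window) return(L)
    for (s in seq_len(L - window + 1)) {
        if (mean(q[s:(s + window - 1)]) < minq) return(s - 1L)
    }
    L
}

# All pseudoknot-free structures of a sequence as lists of pair matrices,
# by exhaustive recursion (feasible for n <= ~14).
rna_pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}
enumerate_structures <- function(seq, min_hairpin = 3) {
    s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
    h <- min_hairpin
    rec <- function(i, j) {
        if (i > j || j - i < h + 1) return(list(matrix(0L, 0, 2)))
        out <- list()
        for (st in rec(i + 1, j)) out[[length(out) + 1]] <- st
        for (k in seq(i + h + 1, j)) {
            if (!rna_pairable(s[i], s[k])) next
            inner <- rec(i + 1, k - 1)
            outer <- rec(k + 1, j)
            for (si in inner) for (so in outer) {
                out[[length(out) + 1]] <- rbind(c(i, k), si, so)
            }
        }
        out
    }
    rec(1, length(s))
}

# Boltzmann ensemble pair probabilities by exhaustive enumeration.
ensemble_oracle <- function(seq, pair_energy = -1, kT = 1,
                            min_hairpin = 3) {
    n <- nchar(seq)
    structs <- enumerate_structures(seq, min_hairpin)
    w <- vapply(structs, function(st) exp(-pair_energy * nrow(st) / kT),
                numeric(1))
    Z <- sum(w)
    P <- matrix(0, n, n)
    for (si in seq_along(structs)) {
        st <- structs[[si]]
        if (nrow(st)) {
            for (r in seq_len(nrow(st))) {
                P[st[r, 1], st[r, 2]] <- P[st[r, 1], st[r, 2]] + w[si] / Z
            }
        }
    }
    P + t(P)
}

random_rna <- function(n) {
    paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
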