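## Fuzzy c-means clustering of standardized log2(FPKM + 1) profiles,
## the soft time-course clustering used for tissue-specific expression
## classes of mobile transcripts.

#' Standardize expression profiles for clustering
#'
#' log2(FPKM + 1) per gene, then z-scored so each row has mean 0 and
#' standard deviation 1. Constant rows carry no profile shape and are
#' excluded (returned in attribute \code{excluded}).
#'
#' @param fpkm genes x samples FPKM matrix (at least 2 samples).
#' @param log_transform apply log2(x + 1) before z-scoring.
#' @return The standardized matrix; dropped constant genes in
#'   \code{attr(, "excluded")}.
#' @export
standardizeProfiles <- function(fpkm, log_transform = TRUE) {
    fpkm <- as.matrix(fpkm)
    if (ncol(fpkm) < 2) stop("need at least 2 samples")
    x <- if (log_transform) log2(fpkm + 1) else fpkm
    s <- apply(x, 1, sd)
    excluded <- rownames(x)[s == 0 | !is.finite(s)]
    keep <- setdiff(rownames(x), excluded)
    x <- x[keep, , drop = FALSE]
    z <- t(scale(t(x)))
    attr(z, "excluded") <- excluded
    z
}

## squared Euclidean distances genes x centers
.d2 <- function(X, V) {
    outer(rowSums(X^2), rep(1, nrow(V))) +
        outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
}

## k-means++-style seeding: first center uniform, then proportional to the
## squared distance to the nearest chosen center.
.init_centers <- function(X, c) {
    n <- nrow(X)
    idx <- integer(c)
    idx[1] <- sample.int(n, 1)
    if (c > 1) {
        for (k in 2:c) {
            d2 <- .d2(X, X[idx[seq_len(k - 1)], , drop = FALSE])
            mind <- pmax(apply(d2, 1, min), 0)
            if (sum(mind) == 0)
                idx[k] <- sample.int(n, 1)
            else
                idx[k] <- sample.int(n, 1, prob = mind)
        }
    }
    X[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering
#'
#' Alternating optimization of the fuzzy objective
#' J = sum_g sum_k u_gk^m d(x_g, v_k)^2: memberships
#' u_gk proportional to (1 / d^2)^{1 / (m - 1)} (row-normalized) and centers
#' v_k = sum_g u_gk^m x_g / sum_g u_gk^m, iterated until the largest center
#' shift drops below \code{tol}. A gene lying exactly on a center receives
#' membership 1 for that center. Initialization is k-means++-style from the
#' seeded RNG, so a fixed seed reproduces the clustering exactly.
#'
#' @param X standardized genes x samples profile matrix.
#' @param c number of clusters (5 is the usual choice for graft
#'   tissue-course profiles).
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on the center shift.
#' @param max_iter iteration cap.
#' @param seed integer RNG seed for initialization.
#' @return A \linkS4class{FuzzyClustering}.
#' @export
fuzzyCMeans <- function(X, c = 5, m = 1.25, tol = 1e-6, max_iter = 1000,
                        seed = 1) {
    X <- as.matrix(X)
    if (any(!is.finite(X))) stop("profiles must be finite")
    if (c < 1) stop("need c >= 1")
    if (m <= 1) stop("fuzzifier m must be > 1")
    if (c > nrow(X)) stop("more clusters than genes")
    set.seed(seed)
    V <- .init_centers(X, c)
    obj <- numeric(0)
    memberships <- function(V) {
        d2 <- pmax(.d2(X, V), 0)
        U <- matrix(0, nrow(X), c)
        zero <- d2 < 1e-300
        has0 <- rowSums(zero) > 0
        if (any(has0)) {
            ## degenerate-distance rule: all mass on the (first) zero center
            first0 <- apply(zero[has0, , drop = FALSE], 1, which.max)
            U[cbind(which(has0), first0)] <- 1
        }
        reg <- !has0
        if (any(reg)) {
            w <- d2[reg, , drop = FALSE]^(-1 / (m - 1))
            U[reg, ] <- w / rowSums(w)
        }
        list(U = U, d2 = d2)
    }
    for (it in seq_len(max_iter)) {
        mb <- memberships(V)
        U <- mb$U
        obj <- c(obj, sum(U^m * mb$d2))
        Um <- U^m
        Vnew <- sweep(t(Um) %*% X, 1, colSums(Um), "/")
        shift <- max(abs(Vnew - V))
        V <- Vnew
        if (shift < tol) break
    }
    mb <- memberships(V)
    obj <- c(obj, sum(mb$U^m * mb$d2))
    hard <- apply(mb$U, 1, which.max)
    rownames(mb$U) <- rownames(X)
    colnames(V) <- colnames(X)
    new("FuzzyClustering", membership = mb$U, centers = V,
        hardAssignment = as.integer(hard), objective = obj, fuzzifier = m)
}

#' Accessors for fuzzy clustering results
#'
#' @param x a \linkS4class{FuzzyClustering}.
#' @return \code{clusterMembership}: the genes x clusters membership
#'   matrix; \code{clusterCenters}: the clusters x samples center matrix;
#'   \code{hardAssignment}: the argmax cluster per gene, named by gene.
#' @export
clusterMembership <- function(x) x@membership

#' @rdname clusterMembership
#' @export
clusterCenters <- function(x) x@centers

#' @rdname clusterMembership
#' @export
hardAssignment <- function(x) {
    setNames(x@hardAssignment, rownames(x@membership))
}
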