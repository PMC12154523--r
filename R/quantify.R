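## Expression quantification and differential calling for mobile-mRNA
## candidates: FPKM, an exact binomial count test with library-size offset,
## Benjamini-Hochberg adjustment and the qPCR 2^-ddCt helper.

#' Compute FPKM from counts
#'
#' FPKM[g, s] = counts[g, s] * 1e9 / (gene_length[g] * library_size[s]).
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param gene_lengths per-gene length in nt (recycled by name when named).
#' @param library_sizes per-sample mapped-read totals.
#' @return A genes x samples FPKM matrix.
#' @examples
#' computeFPKM(matrix(1000), 1000, 1e6)   # 1000
#' @export
computeFPKM <- function(counts, gene_lengths, library_sizes) {
    counts <- as.matrix(counts)
    if (!is.null(names(gene_lengths)) && !is.null(rownames(counts)))
        gene_lengths <- gene_lengths[rownames(counts)]
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
    if (any(library_sizes <= 0)) stop("library sizes must be positive")
    if (any(counts < 0)) stop("counts must be non-negative")
    sweep(sweep(counts, 1, gene_lengths, "/"), 2, library_sizes, "/") * 1e9
}

## Two-sided exact binomial p-value: the sum of P(X = i) over outcomes no
## more probable than the observed one (the classical exact two-sided rule).
.binom_p2 <- function(x, n, p) {
    if (n == 0) return(1)
    d0 <- dbinom(x, n, p)
    ## tolerance factor guards against ties lost to floating point
    sum(dbinom(0:n, n, p)[dbinom(0:n, n, p) <= d0 * (1 + 1e-7)])
}

#' Call differential genes between two groups
#'
#' The log2 fold change is computed on pseudocounted mean FPKM,
#' log2((mean FPKM_A + 1) / (mean FPKM_B + 1)). The per-gene p-value comes
#' from an exact binomial test of the gene's pooled count in group A out of
#' the pooled A+B total against the library-size-expected proportion;
#' p-values are Benjamini-Hochberg adjusted, and a gene is flagged
#' significant when |log2FC| >= lfc_min and FDR <= fdr_max (1 and 0.05 by
#' default, the usual mobile-mRNA thresholds).
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths per-gene lengths in nt.
#' @param library_sizes per-sample library sizes.
#' @param group_a,group_b column names or indices of the two groups.
#' @param lfc_min,fdr_max significance thresholds.
#' @return A data.frame with gene_id, log2_fc, p_value, fdr,
#'   is_significant.
#' @export
callDifferential <- function(counts, gene_lengths, library_sizes,
                             group_a, group_b, lfc_min = 1,
                             fdr_max = 0.05) {
    counts <- as.matrix(counts)
    if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
    if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
    if (length(group_a) < 1 || length(group_b) < 1 ||
        anyNA(c(group_a, group_b)))
        stop("each group needs at least one valid sample")
    fpkm <- computeFPKM(counts, gene_lengths, library_sizes)
    mean_a <- rowMeans(fpkm[, group_a, drop = FALSE])
    mean_b <- rowMeans(fpkm[, group_b, drop = FALSE])
    lfc <- log2((mean_a + 1) / (mean_b + 1))
    lib_a <- sum(library_sizes[group_a])
    lib_b <- sum(library_sizes[group_b])
    p0 <- lib_a / (lib_a + lib_b)
    a <- rowSums(counts[, group_a, drop = FALSE])
    tot <- a + rowSums(counts[, group_b, drop = FALSE])
    pv <- vapply(seq_along(a),
                 function(i) .binom_p2(a[i], tot[i], p0), numeric(1))
    pv <- pmin(pv, 1)
    fdr <- benjaminiHochberg(pv)
    data.frame(gene_id = rownames(counts), log2_fc = unname(lfc),
               p_value = unname(pv), fdr = unname(fdr),
               is_significant = unname(abs(lfc) >= lfc_min &
                                       fdr <= fdr_max),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment controlling the false discovery rate:
#' on sorted p-values, q(i) = min over j >= i of (m / j) p(j), capped at 1,
#' returned in the original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return The adjusted p-values.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,sample - Ct_reference,sample) -
#' (Ct_target,calibrator - Ct_reference,calibrator); relative expression is
#' 2^-ddCt, so one extra cycle of the target in the test sample halves the
#' estimate.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the test sample.
#' @param ct_target_calibrator,ct_ref_calibrator same in the calibrator.
#' @return Relative expression 2^-ddCt.
#' @examples
#' deltaDeltaCt(25, 20, 24, 20)  # 0.5
#' @export
deltaDeltaCt <- function(ct_target_sample, ct_ref_sample,
                         ct_target_calibrator, ct_ref_calibrator) {
    stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
              is.finite(ct_target_calibrator), is.finite(ct_ref_calibrator))
    ddct <- (ct_target_sample - ct_ref_sample) -
        (ct_target_calibrator - ct_ref_calibrator)
    2^(-ddct)
}
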