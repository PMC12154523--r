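## Term enrichment for mobile-mRNA candidate sets against user-supplied
## gene-to-term annotations (functional catalogs are supplied by the user;
## the background is the quantified gene universe).

#' One-sided hypergeometric term enrichment
#'
#' For a term annotating K genes of the universe (size N), of which k fall
#' in the query set (size n), the over-representation p-value is the upper
#' hypergeometric tail P(X >= k). Terms with K = 0 are skipped; p-values
#' are Benjamini-Hochberg adjusted across terms.
#'
#' @param gene_set character vector of query genes (must lie in
#'   \code{universe}).
#' @param annotation data.frame with columns \code{gene} and \code{term}.
#' @param universe background gene ids.
#' @return A data.frame with term, K (annotated in universe), k (in set),
#'   p_value and fdr, sorted by p-value.
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:5), term = "T1")
#' hypergeometricEnrichment(paste0("g", 1:5), ann, paste0("g", 1:20))
#' @export
hypergeometricEnrichment <- function(gene_set, annotation, universe) {
    if (!all(gene_set %in% universe))
        stop("gene_set must be a subset of the universe")
    annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
    N <- length(unique(universe))
    n <- length(unique(gene_set))
    terms <- unique(annotation$term)
    res <- lapply(terms, function(tm) {
        genes_tm <- unique(annotation$gene[annotation$term == tm])
        K <- length(genes_tm)
        if (K == 0) return(NULL)
        k <- sum(gene_set %in% genes_tm)
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = tm, K = K, k = k, p_value = p,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    if (is.null(res))
        return(data.frame(term = character(), K = integer(), k = integer(),
                          p_value = numeric(), fdr = numeric()))
    res$fdr <- benjaminiHochberg(res$p_value)
    res[order(res$p_value), ]
}
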