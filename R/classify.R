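## Two-stage mobile-read classification: quality trimming, scion mapping,
## rescue of unmapped reads against the rootstock reference under the
## identity rule, and homograft false-positive subtraction.

#' Sliding-window quality trimming
#'
#' Scanning 5' to 3', each read is cut before the first window whose mean
#' Phred quality falls below the threshold; reads shorter than the minimum
#' length after cutting are discarded. Reads shorter than the window are
#' kept untouched (no window can fail).
#'
#' @param reads list with \code{id}, \code{seq}, \code{qual} (Phred+33).
#' @param params a \linkS4class{TrimParams}.
#' @return The trimmed read list; discarded reads are removed. The number
#'   discarded is attached as attribute \code{n_discarded}.
#' @examples
#' r <- list(id = "r1", seq = strrep("A", 100), qual = strrep("I", 100))
#' trimReads(r, trimParams())$seq
#' @export
trimReads <- function(reads, params = trimParams()) {
    validObject(params)
    if (length(reads$seq) == 0) {
        out <- list(id = character(), seq = character(), qual = character())
        attr(out, "n_discarded") <- 0L
        return(out)
    }
    if (any(nchar(reads$seq) != nchar(reads$qual)))
        stop("sequence and quality lengths differ")
    keep_len <- .trim_lengths_cpp(reads$qual, as.integer(params@window),
                                  params@minMeanQuality, 33L)
    keep <- keep_len >= params@minLength
    out <- list(id = reads$id[keep],
                seq = substr(reads$seq[keep], 1L, keep_len[keep]),
                qual = substr(reads$qual[keep], 1L, keep_len[keep]))
    attr(out, "n_discarded") <- sum(!keep)
    out
}

#' Banded global alignment of two sequences
#'
#' Needleman-Wunsch alignment restricted to a diagonal band (the band is
#' widened by the length difference so a global path always exists).
#' Identity is matching columns over alignment columns; coverage is the
#' fraction of the first sequence aligned opposite bases of the second.
#'
#' @param a,b character sequences (a is the read).
#' @param band band half-width.
#' @param match,mismatch,gap alignment scores.
#' @param fit free end-gaps in \code{b} (global in \code{a}, local in
#'   \code{b}); the mode used to fit a read into a reference window.
#' @return A list with score, matches, columns, identity and coverage.
#' @examples
#' nwAlign("ACGT", "ACGT")$identity
#' @export
nwAlign <- function(a, b, band = 1e6, match = 1, mismatch = -1, gap = -2,
                    fit = FALSE) {
    .nw_align_cpp(a, b, as.integer(min(band, nchar(a) + nchar(b))),
                  match, mismatch, gap, fit)
}

#' Align a read against a reference gene set
#'
#' k-mer seeding on both strands followed by banded global alignment over
#' the seeded window; returns the highest-scoring hit with deterministic
#' tie-breaking (lexicographically smallest target gene id, then the
#' + strand).
#'
#' @param read a read sequence (character).
#' @param reference a named \link[Biostrings]{DNAStringSet} (or named
#'   character vector) of gene sequences.
#' @param params a \linkS4class{ClassificationParams} (supplies seed k-mer
#'   size, band and scores).
#' @return A one-row data.frame (read_id-free \code{AlignmentHit}: target
#'   gene, identity, coverage, score, strand), or \code{NULL} when the read
#'   is shorter than the seed or shares no k-mer with the reference.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(g1 = strrep("ACGTT", 30)))
#' alignRead(substr(strrep("ACGTT", 30), 10, 69), ref)
#' @export
alignRead <- function(read, reference, params = classificationParams()) {
    if (length(reference) == 0) stop("empty reference")
    hits <- .align_reads(read, reference, params)
    if (is.na(hits$target[1])) return(NULL)
    data.frame(target_gene = hits$gene[1], identity = hits$identity[1],
               coverage = hits$coverage[1], score = hits$score[1],
               strand = hits$strand[1], stringsAsFactors = FALSE)
}

## Batch alignment; refs are sorted by name so C++ index-order ties equal
## lexicographic gene-id ties.
.align_reads <- function(seqs, reference, params) {
    refseq <- as.character(reference)
    nm <- names(reference)
    if (is.null(nm)) stop("reference must be named")
    ord <- order(nm, method = "radix")
    refseq <- refseq[ord]; nm <- nm[ord]
    df <- .align_batch_cpp(seqs, unname(refseq),
                           as.integer(params@seedK),
                           as.integer(params@band),
                           params@matchScore, params@mismatchScore,
                           params@gapScore)
    df$gene <- ifelse(is.na(df$target), NA_character_, nm[df$target])
    df
}

#' Classify the reads of one sample
#'
#' A read is scion-mapped when its best scion hit reaches the scion
#' identity and coverage thresholds; only reads failing that are aligned to
#' the rootstock reference, and those meeting the rootstock thresholds
#' (identity >= 0.95 over >= 0.80 of the read by default) increment the
#' candidate count of their best rootstock gene.
#'
#' For paired-end input (elements \code{seq2}/\code{qual2} present), mates
#' are classified independently and each fragment counts once, to the mate
#' with the stronger rootstock hit (ties go to mate 1).
#'
#' @param reads list with \code{id}, \code{seq}, \code{qual} (and
#'   optionally \code{seq2}, \code{qual2}), or a FASTQ path.
#' @param scion_ref,rootstock_ref named references with disjoint gene ids.
#' @param params a \linkS4class{ClassificationParams}.
#' @param trim a \linkS4class{TrimParams}, or NULL to skip trimming.
#' @return A list with \code{counts} (named integer vector over rootstock
#'   genes) and \code{accounting} (one-row data.frame: clean_reads,
#'   scion_mapped, scion_mapped_rate, unmapped, rootstock_mapped,
#'   rootstock_mapped_rate computed on reads submitted to the rescue stage,
#'   and rootstock_overall_rate computed on clean reads).
#' @export
classifySample <- function(reads, scion_ref, rootstock_ref,
                           params = classificationParams(),
                           trim = trimParams()) {
    if (is.character(reads) && length(reads) == 1)
        reads <- readFastq(reads)
    if (length(intersect(names(scion_ref), names(rootstock_ref))))
        stop("scion and rootstock references share gene ids")
    root_genes <- sort(names(rootstock_ref))
    paired <- !is.null(reads$seq2)
    classify_mates <- function(seqs) {
        n <- length(seqs)
        res <- list(scion_mapped = logical(n),
                    root_gene = rep(NA_character_, n),
                    root_score = rep(-Inf, n))
        if (n == 0) return(res)
        sc <- .align_reads(seqs, scion_ref, params)
        res$scion_mapped <- !is.na(sc$target) &
            sc$identity >= params@scionIdentityMin &
            sc$coverage >= params@scionCoverageMin
        un <- which(!res$scion_mapped)
        if (length(un)) {
            rs <- .align_reads(seqs[un], rootstock_ref, params)
            ok <- !is.na(rs$target) &
                rs$identity >= params@rootstockIdentityMin &
                rs$coverage >= params@rootstockCoverageMin
            res$root_gene[un[ok]] <- rs$gene[ok]
            res$root_score[un[ok]] <- rs$score[ok]
        }
        res
    }
    if (!paired) {
        if (!is.null(trim)) reads <- trimReads(reads, trim)
        n <- length(reads$seq)
        m1 <- classify_mates(reads$seq)
        scion_mapped <- m1$scion_mapped
        root_gene <- m1$root_gene
    } else {
        ## mates trimmed and classified independently; fragment survives if
        ## either mate survives trimming (the surviving mate represents it)
        keep1 <- rep(TRUE, length(reads$seq))
        if (!is.null(trim)) {
            t1 <- trimReads(list(id = reads$id, seq = reads$seq,
                                 qual = reads$qual), trim)
            t2 <- trimReads(list(id = reads$id, seq = reads$seq2,
                                 qual = reads$qual2), trim)
            k1 <- reads$id %in% t1$id
            k2 <- reads$id %in% t2$id
            frag <- k1 | k2
            s1 <- ifelse(k1, reads$seq, "")[frag]
            s2 <- ifelse(k2, reads$seq2, "")[frag]
        } else {
            s1 <- reads$seq; s2 <- reads$seq2
            frag <- rep(TRUE, length(s1))
        }
        n <- sum(frag)
        m1 <- classify_mates(s1)
        m2 <- classify_mates(s2)
        scion_mapped <- m1$scion_mapped | m2$scion_mapped
        use2 <- !scion_mapped & m2$root_score > m1$root_score
        root_gene <- ifelse(use2, m2$root_gene, m1$root_gene)
        root_gene[scion_mapped] <- NA_character_
    }
    counts <- integer(length(root_genes))
    names(counts) <- root_genes
    if (n > 0) {
        tab <- table(root_gene[!is.na(root_gene)])
        counts[names(tab)] <- as.integer(tab)
    }
    clean <- n
    scion_n <- sum(scion_mapped)
    unmapped <- clean - scion_n
    root_n <- sum(counts)
    accounting <- data.frame(
        clean_reads = clean,
        scion_mapped = scion_n,
        scion_mapped_rate = if (clean > 0) mappedRate(scion_n, clean) else 0,
        unmapped = unmapped,
        rootstock_mapped = root_n,
        rootstock_mapped_rate = if (unmapped > 0)
            mappedRate(root_n, unmapped) else 0,
        rootstock_overall_rate = if (clean > 0)
            mappedRate(root_n, clean) else 0)
    list(counts = counts, accounting = accounting)
}

#' Classify every sample of a simulated or on-disk experiment
#'
#' Runs \code{\link{classifySample}} over a sample sheet and assembles the
#' per-gene candidate counts into a
#' \link[SummarizedExperiment]{SummarizedExperiment} (rootstock genes x
#' samples) whose \code{colData} carries the sample sheet and the read
#' accounting.
#'
#' @param x a \linkS4class{GraftSimulation}, or a sample sheet data.frame
#'   with a \code{fastq} column of file paths.
#' @param scion_ref,rootstock_ref references; taken from the simulation
#'   when \code{x} is a \linkS4class{GraftSimulation}.
#' @param params a \linkS4class{ClassificationParams}.
#' @param trim a \linkS4class{TrimParams}, or NULL to skip trimming.
#' @return A SummarizedExperiment with assay \code{candidate_counts}.
#' @export
classifyExperiment <- function(x, scion_ref = NULL, rootstock_ref = NULL,
                               params = classificationParams(),
                               trim = trimParams()) {
    if (is(x, "GraftSimulation")) {
        samples <- x@samples
        scion_ref <- x@scion
        rootstock_ref <- x@rootstock
        get_reads <- function(i) x@reads[[samples$sample_id[i]]]
    } else {
        samples <- x
        if (is.null(scion_ref) || is.null(rootstock_ref))
            stop("references are required with a sample sheet")
        get_reads <- function(i) readFastq(samples$fastq[i])
    }
    root_genes <- sort(names(rootstock_ref))
    counts <- matrix(0L, nrow = length(root_genes), ncol = nrow(samples),
                     dimnames = list(root_genes, samples$sample_id))
    acc <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
        cl <- classifySample(get_reads(i), scion_ref, rootstock_ref,
                             params, trim)
        counts[, i] <- cl$counts
        acc[[i]] <- cl$accounting
    }
    cd <- cbind(samples, do.call(rbind, acc))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(candidate_counts = counts),
        colData = S4Vectors::DataFrame(cd, row.names = samples$sample_id))
}

#' Subtract homograft false positives
#'
#' Any rootstock gene whose candidate count reaches the detection threshold
#' in any homograft control sample is removed from all heterograft tables;
#' the survivors constitute the mobile-mRNA candidate set.
#'
#' @param se a SummarizedExperiment from \code{\link{classifyExperiment}}
#'   (colData must contain \code{graft_type}).
#' @param params a \linkS4class{ClassificationParams} (supplies the
#'   detection threshold).
#' @return A list with \code{mobile_genes} (rootstock genes detected in at
#'   least one heterograft sample and in no homograft control),
#'   \code{excluded} (genes removed by the control filter), and
#'   \code{filtered} (the heterograft-sample SummarizedExperiment restricted
#'   to surviving genes).
#' @export
subtractHomograft <- function(se, params = classificationParams()) {
    counts <- SummarizedExperiment::assay(se, "candidate_counts")
    gt <- SummarizedExperiment::colData(se)$graft_type
    if (is.null(gt)) stop("colData lacks graft_type")
    homo <- gt == "homo"
    hetero <- gt == "hetero"
    if (!any(homo)) {
        warning("no homograft controls: all genes pass the filter")
        excluded <- character()
    } else {
        hmax <- apply(counts[, homo, drop = FALSE], 1, max)
        excluded <- rownames(counts)[hmax >=
                                     params@homograftDetectionThreshold]
    }
    keep <- setdiff(rownames(counts), excluded)
    hcounts <- counts[keep, hetero, drop = FALSE]
    mobile <- rownames(hcounts)[rowSums(hcounts) > 0]
    list(mobile_genes = mobile, excluded = excluded,
         filtered = se[keep, hetero])
}

#' Mapped rate as printed in read-accounting tables
#'
#' 100 * mapped / clean, rounded half away from zero to 2 decimals (the
#' rounding used in sequencing summary tables).
#'
#' @param mapped,clean read counts with \code{0 <= mapped <= clean},
#'   \code{clean > 0}.
#' @return The rate in percent, a numeric rounded to 2 decimals.
#' @examples
#' mappedRate(32064, 8828672)   # 0.36
#' @export
mappedRate <- function(mapped, clean) {
    if (any(clean <= 0)) stop("clean read count must be positive")
    if (any(mapped < 0 | mapped > clean))
        stop("need 0 <= mapped <= clean")
    x <- 100 * mapped / clean
    sign(x) * floor(abs(x) * 100 + 0.5) / 100
}
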