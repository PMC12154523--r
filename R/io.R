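## File I/O helpers: FASTQ via Biostrings, Vienna dot-bracket, TSV exports.

#' Read and write FASTQ files
#'
#' Reads are held in memory as a list of parallel character vectors
#' \code{id}, \code{seq} and \code{qual} (Sanger Phred+33), the
#' representation every classification function accepts.
#'
#' @param path a FASTQ file path.
#' @return \code{readFastq} returns a list with \code{id}, \code{seq} and
#'   \code{qual} character vectors.
#' @export
readFastq <- function(path) {
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    list(id = names(x),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
}

#' @rdname readFastq
#' @param reads a list with \code{id}, \code{seq}, \code{qual}.
#' @export
writeFastq <- function(reads, path) {
    n <- length(reads$seq)
    stopifnot(length(reads$id) == n, length(reads$qual) == n)
    con <- file(path, "wb")            # binary mode: byte-stable newlines
    on.exit(close(con))
    if (n) {
        lines <- character(4L * n)
        lines[seq(1, 4 * n, 4)] <- paste0("@", reads$id)
        lines[seq(2, 4 * n, 4)] <- reads$seq
        lines[seq(3, 4 * n, 4)] <- "+"
        lines[seq(4, 4 * n, 4)] <- reads$qual
        writeLines(lines, con, sep = "\n")
    }
    invisible(path)
}

#' Write a structure in Vienna dot-bracket format
#'
#' @param x a \linkS4class{DotBracketStructure}.
#' @param path output file.
#' @param name FASTA-style header for the record.
#' @return Invisibly, the path.
#' @export
writeVienna <- function(x, path, name = "structure") {
    writeLines(c(paste0(">", name), x@sequence, x@structure), path)
    invisible(path)
}

#' Write a TSV table
#'
#' Thin wrapper fixing the conventions used throughout the package
#' (tab-separated, no quoting, no row names).
#'
#' @param x a data.frame or matrix.
#' @param path output file.
#' @param rownames_as column name under which to emit row names, or NULL.
#' @return Invisibly, the path.
#' @export
writeTsv <- function(x, path, rownames_as = NULL) {
    if (!is.null(rownames_as)) {
        x <- data.frame(setNames(list(rownames(x)), rownames_as),
                        as.data.frame(x), check.names = FALSE,
                        stringsAsFactors = FALSE)
    }
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
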