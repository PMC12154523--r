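## Synthetic heterograft experiment generator.
##
## Ancestor genes are i.i.d. uniform over ACGT; the scion copy is the
## ancestor, the rootstock copy carries round((1 - identity) * L)
## substitutions at positions sampled without replacement, so the realized
## per-site identity matches the target to within rounding. Divergence is by
## point substitution only, which keeps identity arithmetic exact.

.rand_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.substitute_sites <- function(seq, k) {
    if (k == 0) return(seq)
    v <- strsplit(seq, "")[[1]]
    pos <- sample.int(length(v), k)
    alt <- c("A", "C", "G", "T")
    for (p in pos) {
        v[p] <- sample(setdiff(alt, v[p]), 1)
    }
    paste(v, collapse = "")
}

#' Generate diverged scion and rootstock gene sets
#'
#' Each ancestor gene yields one scion copy and one rootstock copy whose
#' realized pairwise identity matches \code{orthologIdentity} to within
#' rounding of the substitution count. Deterministic under the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A list with \code{scion} and \code{rootstock}
#'   \link[Biostrings]{DNAStringSet}s and an \code{orthologMap} data.frame
#'   (scion_gene, rootstock_gene, length, n_substitutions).
#' @examples
#' gs <- generateGeneSets(simulationConfig(nGenes = 5, seed = 1))
#' length(gs$scion)
#' @export
generateGeneSets <- function(config) {
    validObject(config)
    set.seed(config@seed)
    n <- config@nGenes
    lens <- sample(seq(config@geneLengthRange[1], config@geneLengthRange[2]),
                   n, replace = TRUE)
    scion_ids <- sprintf("SCg%04d", seq_len(n))
    root_ids <- sprintf("RSg%04d", seq_len(n))
    scion <- character(n)
    rootstock <- character(n)
    nsub <- integer(n)
    for (i in seq_len(n)) {
        anc <- .rand_dna(lens[i])
        scion[i] <- anc
        nsub[i] <- round((1 - config@orthologIdentity) * lens[i])
        rootstock[i] <- .substitute_sites(anc, nsub[i])
    }
    scion_set <- Biostrings::DNAStringSet(scion)
    names(scion_set) <- scion_ids
    root_set <- Biostrings::DNAStringSet(rootstock)
    names(root_set) <- root_ids
    list(scion = scion_set, rootstock = root_set,
         orthologMap = data.frame(scion_gene = scion_ids,
                                  rootstock_gene = root_ids,
                                  length = lens, n_substitutions = nsub,
                                  stringsAsFactors = FALSE))
}

.quality_char <- function(error_rate) {
    q <- if (error_rate <= 0) 40L else
        min(40L, as.integer(round(-10 * log10(error_rate))))
    rawToChar(as.raw(33L + q))
}

## Draw reads for one sample. Transcript pool: scion genes with relative
## abundance (1 - m), planted mobile rootstock genes with relative abundance
## m (m = 0 for homografts). Read names carry a provenance suffix
## "|og=<gene>|gn=<genome>" that classifiers must never read.
.simulate_sample_reads <- function(sample_id, mobility, config,
                                   scion, rootstock, mobile_ids,
                                   scion_abund, mobile_abund) {
    nr <- config@readsPerSample
    rl <- config@readLength
    n_rs <- if (mobility > 0) rbinom(1, nr, mobility) else 0L
    n_sc <- nr - n_rs
    pick_reads <- function(refset, ids, abund, count, genome) {
        if (count == 0)
            return(list(gene = character(), seq = character()))
        lens <- Biostrings::width(refset)[match(ids, names(refset))]
        usable <- lens >= rl
        if (!any(usable)) stop("no transcript long enough for read length")
        ids <- ids[usable]; abund <- abund[usable]; lens <- lens[usable]
        gi <- sample.int(length(ids), count, replace = TRUE,
                         prob = abund)
        starts <- floor(runif(count) * (lens[gi] - rl + 1)) + 1L
        seqs <- as.character(Biostrings::subseq(refset[ids[gi]],
                                                start = starts,
                                                width = rl))
        ## unstranded library: half the reads on the reverse strand
        rev <- runif(count) < 0.5
        if (any(rev))
            seqs[rev] <- as.character(
                Biostrings::reverseComplement(
                    Biostrings::DNAStringSet(seqs[rev])))
        list(gene = ids[gi], seq = unname(seqs))
    }
    sc <- pick_reads(scion, names(scion), scion_abund, n_sc, "scion")
    rs <- pick_reads(rootstock, mobile_ids, mobile_abund, n_rs, "rootstock")
    gene <- c(sc$gene, rs$gene)
    genome <- rep(c("scion", "rootstock"), c(length(sc$gene),
                                             length(rs$gene)))
    seqs <- c(sc$seq, rs$seq)
    ord <- sample.int(length(seqs))          # shuffle origin blocks
    gene <- gene[ord]; genome <- genome[ord]; seqs <- seqs[ord]
    seqs <- .mutate_reads_cpp(seqs, config@errorRate)
    qc <- .quality_char(config@errorRate)
    ids <- sprintf("%s:rd%06d|og=%s|gn=%s", sample_id,
                   seq_along(seqs), gene, genome)
    out <- list(id = ids, seq = seqs,
                qual = rep(strrep(qc, rl), length(seqs)),
                origin_gene = gene, origin_genome = genome)
    if (config@paired) {
        ## mate 2 is the reverse complement of the same fragment
        out$seq2 <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(out$seq)))
        out$qual2 <- out$qual
    }
    out
}

#' Simulate a complete graft experiment
#'
#' Generates the diverged references, plants a mobile gene set, builds the
#' homograft/heterograft by pulp/stem sample sheet with replicates, and
#' simulates reads per sample with substitution errors. The heterograft
#' rootstock-origin read count per sample is Binomial(readsPerSample,
#' mobility factor of the tissue); homograft samples draw only from scion
#' transcripts. All randomness flows from the config seed, so regeneration
#' is byte-identical.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{GraftSimulation}.
#' @examples
#' sim <- simulateGraftExperiment(
#'     simulationConfig(nGenes = 20, readsPerSample = 500,
#'                      geneLengthRange = c(200, 400), nMobile = 3, seed = 7))
#' sim
#' @export
simulateGraftExperiment <- function(config) {
    validObject(config)
    gs <- generateGeneSets(config)        # seeds the RNG with config@seed
    mobile_ids <- sort(sample(names(gs$rootstock), config@nMobile))
    ## per-gene relative abundances (gamma draws, fixed across samples)
    scion_abund <- rgamma(length(gs$scion), shape = 2, rate = 1)
    scion_abund <- scion_abund / sum(scion_abund)
    mobile_abund <- rgamma(length(mobile_ids), shape = 2, rate = 1)
    mobile_abund <- mobile_abund / sum(mobile_abund)

    conditions <- expand.grid(replicate = seq_len(config@nReplicates),
                              tissue = c("far", "near"),
                              graft_type = c("homo", "hetero"),
                              stringsAsFactors = FALSE)
    ## XG homograft pulp, XJ homograft stem, YG heterograft pulp,
    ## YJ heterograft stem
    code <- with(conditions, paste0(ifelse(graft_type == "homo", "X", "Y"),
                                    ifelse(tissue == "far", "G", "J")))
    samples <- data.frame(sample_id = paste0(code, "_",
                                             conditions$replicate),
                          graft_type = conditions$graft_type,
                          tissue = conditions$tissue,
                          replicate = conditions$replicate,
                          stringsAsFactors = FALSE)
    all_genes <- c(names(gs$scion), names(gs$rootstock))
    origin_counts <- matrix(0L, nrow = length(all_genes),
                            ncol = nrow(samples),
                            dimnames = list(all_genes, samples$sample_id))
    reads <- vector("list", nrow(samples))
    names(reads) <- samples$sample_id
    for (i in seq_len(nrow(samples))) {
        m <- if (samples$graft_type[i] == "homo") 0 else
            if (samples$tissue[i] == "near") config@mobilityNear else
                config@mobilityFar
        rd <- .simulate_sample_reads(samples$sample_id[i], m, config,
                                     gs$scion, gs$rootstock, mobile_ids,
                                     scion_abund, mobile_abund)
        tab <- table(rd$origin_gene)
        origin_counts[names(tab), i] <- as.integer(tab)
        reads[[i]] <- rd[c("id", "seq", "qual", "seq2",
                           "qual2")[c(TRUE, TRUE, TRUE, config@paired,
                                      config@paired)]]
        reads[[i]]$origin_gene <- rd$origin_gene
        reads[[i]]$origin_genome <- rd$origin_genome
    }
    abundance <- data.frame(gene = c(names(gs$scion), mobile_ids),
                            genome = rep(c("scion", "rootstock"),
                                         c(length(gs$scion),
                                           length(mobile_ids))),
                            relative_abundance = c(scion_abund,
                                                   mobile_abund),
                            stringsAsFactors = FALSE)
    new("GraftSimulation", config = config, scion = gs$scion,
        rootstock = gs$rootstock, orthologMap = gs$orthologMap,
        samples = samples, reads = reads,
        truth = list(mobile_gene_ids = mobile_ids,
                     origin_counts = origin_counts,
                     abundance = abundance))
}

#' @rdname simulateGraftExperiment
#' @param sim a \linkS4class{GraftSimulation}.
#' @export
sampleSheet <- function(sim) sim@samples

#' @rdname simulateGraftExperiment
#' @export
groundTruth <- function(sim) sim@truth

#' @rdname simulateGraftExperiment
#' @export
scionReference <- function(sim) sim@scion

#' @rdname simulateGraftExperiment
#' @export
rootstockReference <- function(sim) sim@rootstock

#' @rdname simulateGraftExperiment
#' @param sample_id a sample id from the sample sheet.
#' @export
sampleReads <- function(sim, sample_id) {
    if (!sample_id %in% names(sim@reads))
        stop("unknown sample id: ", sample_id)
    sim@reads[[sample_id]]
}

#' Simulate metabolite abundances coupled to transcript profiles
#'
#' Each requested coupling produces a metabolite whose profile is a signed,
#' standardized monotone transform of the gene's expression plus Gaussian
#' noise, so with \code{noise_sd = 0} the realized Spearman correlation is
#' exactly +1 or -1 according to the sign of the target. For a target
#' magnitude |rho| < 1, \code{noiseForTargetRho} gives the noise standard
#' deviation for which the expected Pearson correlation on standardized
#' scores equals the target.
#'
#' @param expression genes x samples abundance matrix (rownames = gene ids).
#' @param couplings data.frame with columns gene, metabolite, rho.
#' @param noise_sd Gaussian noise standard deviation added to the
#'   standardized coupled profile.
#' @param seed integer RNG seed.
#' @param n_background number of additional uncoupled metabolites with
#'   independent Gaussian profiles.
#' @return A metabolites x samples matrix.
#' @examples
#' expr <- matrix(1:12, 2, 6, dimnames = list(c("g1", "g2"), NULL))
#' m <- simulateMetabolites(expr,
#'     data.frame(gene = "g1", metabolite = "met1", rho = 1), 0, seed = 1)
#' cor(m["met1", ], expr["g1", ], method = "spearman")
#' @export
simulateMetabolites <- function(expression, couplings, noise_sd = 0,
                                seed = 1, n_background = 0) {
    if (ncol(expression) < 4)
        stop("need at least 4 samples for metabolite coupling")
    if (any(abs(couplings$rho) > 1))
        stop("|target rho| must be <= 1")
    set.seed(seed)
    ns <- ncol(expression)
    out <- matrix(0, nrow = nrow(couplings) + n_background, ncol = ns)
    rn <- character(nrow(couplings) + n_background)
    for (i in seq_len(nrow(couplings))) {
        g <- couplings$gene[i]
        if (!g %in% rownames(expression))
            stop("coupling gene not in expression matrix: ", g)
        x <- as.numeric(expression[g, ])
        z <- if (sd(x) == 0) rep(0, ns) else (x - mean(x)) / sd(x)
        out[i, ] <- sign(couplings$rho[i]) * z + noise_sd * rnorm(ns)
        rn[i] <- couplings$metabolite[i]
    }
    if (n_background > 0) {
        idx <- nrow(couplings) + seq_len(n_background)
        out[idx, ] <- matrix(rnorm(n_background * ns), n_background, ns)
        rn[idx] <- sprintf("bgmet%03d", seq_len(n_background))
    }
    dimnames(out) <- list(rn, colnames(expression))
    out
}

#' @rdname simulateMetabolites
#' @param rho target correlation magnitude in (0, 1].
#' @export
noiseForTargetRho <- function(rho) {
    stopifnot(rho > 0, rho <= 1)
    sqrt(1 / rho^2 - 1)
}

#' Write simulated references, reads and metadata to disk
#'
#' Writes scion/rootstock FASTA, per-sample FASTQ (Sanger Phred+33), a TSV
#' sample sheet and a TSV ground-truth table. Output is byte-identical for
#' identical simulations.
#'
#' @param sim a \linkS4class{GraftSimulation}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(scion = file.path(outdir, "scion.fa"),
               rootstock = file.path(outdir, "rootstock.fa"),
               samples = file.path(outdir, "samples.tsv"),
               truth = file.path(outdir, "mobile_truth.tsv"))
    Biostrings::writeXStringSet(sim@scion, paths["scion"])
    Biostrings::writeXStringSet(sim@rootstock, paths["rootstock"])
    ss <- sim@samples
    ss$fastq <- file.path(outdir, paste0(ss$sample_id, ".fastq"))
    for (i in seq_len(nrow(ss))) {
        rd <- sim@reads[[ss$sample_id[i]]]
        writeFastq(rd, ss$fastq[i])
        if (!is.null(rd$seq2)) {
            mate2 <- list(id = rd$id, seq = rd$seq2, qual = rd$qual2)
            writeFastq(mate2, sub("\\.fastq$", "_2.fastq", ss$fastq[i]))
        }
    }
    write.table(ss, paths["samples"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene = sim@truth$mobile_gene_ids),
                paths["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(paths, ss$fastq))
}
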