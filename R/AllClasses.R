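#' Simulation configuration for a synthetic graft experiment
#'
#' Parameters of the synthetic heterograft/homograft generator: a set of
#' ancestor genes is diverged into a scion and a rootstock copy at a
#' controlled per-site identity; a chosen subset of rootstock genes is
#' planted as mobile, contributing a tissue-dependent fraction of the scion
#' read pool (larger near the graft union, i.e. stem, than far from it,
#' i.e. pulp); reads receive substitution errors at a fixed per-base rate.
#'
#' @slot nGenes number of ancestor genes (ortholog pairs).
#' @slot geneLengthRange min and max gene length in nt.
#' @slot orthologIdentity target scion/rootstock per-site identity in (0, 1].
#' @slot nMobile number of rootstock genes planted as mobile.
#' @slot mobilityNear fraction of the scion-tissue read pool of rootstock
#'   origin in near tissue (stem).
#' @slot mobilityFar same for far tissue (pulp); must not exceed
#'   \code{mobilityNear}.
#' @slot readsPerSample reads (or read pairs) per sample.
#' @slot readLength read length in nt.
#' @slot errorRate per-base substitution probability.
#' @slot paired simulate paired-end reads.
#' @slot nReplicates replicates per graft-by-tissue condition.
#' @slot seed integer RNG seed.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nGenes = "numeric",
        geneLengthRange = "numeric",
        orthologIdentity = "numeric",
        nMobile = "numeric",
        mobilityNear = "numeric",
        mobilityFar = "numeric",
        readsPerSample = "numeric",
        readLength = "numeric",
        errorRate = "numeric",
        paired = "logical",
        nReplicates = "numeric",
        seed = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@orthologIdentity <= 0 || object@orthologIdentity > 1)
        msg <- c(msg, "orthologIdentity must be in (0, 1]")
    if (object@mobilityFar < 0 || object@mobilityFar > object@mobilityNear ||
        object@mobilityNear >= 1)
        msg <- c(msg, "need 0 <= mobilityFar <= mobilityNear < 1")
    counts <- c(object@nGenes, object@nMobile, object@readsPerSample,
                object@readLength, object@nReplicates)
    if (any(counts <= 0) || any(counts != round(counts)))
        msg <- c(msg, "all counts must be positive integers")
    if (length(object@geneLengthRange) != 2 ||
        object@geneLengthRange[1] > object@geneLengthRange[2])
        msg <- c(msg, "geneLengthRange must be c(min, max) with min <= max")
    if (object@geneLengthRange[1] < 20)
        msg <- c(msg, "gene length below 20 nt cannot hold the identity target")
    if (object@nMobile > object@nGenes)
        msg <- c(msg, "nMobile cannot exceed nGenes")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the study design the generator emulates: 200 ortholog
#' pairs at 85\% identity (cucurbit-like homology), 20 planted mobile genes,
#' a 2\% rootstock fraction in stem and 0.4\% in pulp, 50,000 single-end
#' 100-nt reads per sample at 0.5\% substitution error, and 3 replicates per
#' condition (12 samples: homograft/heterograft x pulp/stem).
#'
#' @param nGenes,geneLengthRange,orthologIdentity,nMobile number and length
#'   of ancestor genes, target ortholog identity, and planted mobile genes.
#' @param mobilityNear,mobilityFar rootstock-origin fraction of the scion
#'   read pool in near (stem) and far (pulp) tissue.
#' @param readsPerSample,readLength,errorRate,paired read simulation
#'   parameters.
#' @param nReplicates replicates per condition.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationConfig} object.
#' @examples
#' cfg <- simulationConfig(nGenes = 20, readsPerSample = 500, seed = 1)
#' @export
simulationConfig <- function(nGenes = 200,
                             geneLengthRange = c(300, 1500),
                             orthologIdentity = 0.85,
                             nMobile = 20,
                             mobilityNear = 0.02,
                             mobilityFar = 0.004,
                             readsPerSample = 50000,
                             readLength = 100,
                             errorRate = 0.005,
                             paired = FALSE,
                             nReplicates = 3,
                             seed = 1) {
    new("SimulationConfig", nGenes = nGenes,
        geneLengthRange = geneLengthRange,
        orthologIdentity = orthologIdentity, nMobile = nMobile,
        mobilityNear = mobilityNear, mobilityFar = mobilityFar,
        readsPerSample = readsPerSample, readLength = readLength,
        errorRate = errorRate, paired = paired, nReplicates = nReplicates,
        seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenes, "ortholog pairs,",
        sprintf("identity %.2f,", object@orthologIdentity),
        object@nMobile, "mobile genes\n")
    cat("  mobility near/far:", object@mobilityNear, "/",
        object@mobilityFar, "\n")
    cat("  reads/sample:", object@readsPerSample,
        sprintf("(%d nt, error %.3g, %s)", as.integer(object@readLength),
                object@errorRate,
                if (object@paired) "paired" else "single"), "\n")
    cat("  replicates:", object@nReplicates, " seed:", object@seed, "\n")
})

#' A simulated graft experiment with ground truth
#'
#' Holds the diverged scion and rootstock references, the sample sheet for
#' the homograft/heterograft by pulp/stem design, the simulated reads and
#' the ground truth (planted mobile genes, per-sample true origin counts and
#' true abundances) used as oracle by the tests.
#'
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot scion,rootstock \link[Biostrings]{DNAStringSet} references.
#' @slot orthologMap data.frame pairing scion and rootstock gene ids.
#' @slot samples sample sheet (sample_id, graft_type, tissue, replicate).
#' @slot reads per-sample list of list(id, seq, qual) character vectors
#'   (plus seq2/qual2 for paired ends).
#' @slot truth list with mobile_gene_ids, origin_counts (gene x sample true
#'   read-origin counts) and abundance (true relative abundances).
#' @exportClass GraftSimulation
setClass("GraftSimulation",
    representation(
        config = "SimulationConfig",
        scion = "ANY",
        rootstock = "ANY",
        orthologMap = "data.frame",
        samples = "data.frame",
        reads = "list",
        truth = "list"
    )
)

setValidity("GraftSimulation", function(object) {
    ss <- object@samples
    msg <- character()
    if (!all(c("sample_id", "graft_type", "tissue", "replicate") %in%
             names(ss)))
        msg <- c(msg, "sample sheet lacks required columns")
    else {
        if (anyDuplicated(ss[c("graft_type", "tissue", "replicate")]))
            msg <- c(msg, "(graft_type, tissue, replicate) must be unique")
        if (!all(ss$graft_type %in% c("hetero", "homo")))
            msg <- c(msg, "graft_type must be 'hetero' or 'homo'")
        if (!all(ss$tissue %in% c("near", "far")))
            msg <- c(msg, "tissue must be 'near' (stem) or 'far' (pulp)")
    }
    if (!all(object@truth$mobile_gene_ids %in% names(object@rootstock)))
        msg <- c(msg, "mobile gene ids must be rootstock gene ids")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GraftSimulation", function(object) {
    cat("GraftSimulation:", nrow(object@samples), "samples,",
        length(object@scion), "scion +", length(object@rootstock),
        "rootstock genes,", length(object@truth$mobile_gene_ids),
        "planted mobile genes\n")
    print(object@samples[, c("sample_id", "graft_type", "tissue",
                             "replicate")], row.names = FALSE)
})

#' Read trimming parameters
#'
#' Sliding-window quality trimming: scanning 5' to 3', the read is cut
#' before the first window whose mean Phred quality drops below the
#' threshold; reads shorter than \code{minLength} after cutting are
#' discarded. Defaults follow the common window 4 / quality 15 /
#' minimum length 75 setting.
#'
#' @slot window window width in bases.
#' @slot minMeanQuality Phred threshold on the window mean.
#' @slot minLength minimum retained read length.
#' @exportClass TrimParams
setClass("TrimParams",
    representation(window = "numeric", minMeanQuality = "numeric",
                   minLength = "numeric"))

setValidity("TrimParams", function(object) {
    if (object@window < 1) return("window must be >= 1")
    if (object@minLength < 1) return("minLength must be >= 1")
    TRUE
})

#' @rdname TrimParams-class
#' @param window,minMeanQuality,minLength see slot descriptions.
#' @return A \linkS4class{TrimParams} object.
#' @export
trimParams <- function(window = 4, minMeanQuality = 15, minLength = 75) {
    new("TrimParams", window = window, minMeanQuality = minMeanQuality,
        minLength = minLength)
}

#' Read classification parameters
#'
#' Thresholds of the two-stage classifier: a read counts as scion-mapped at
#' or above the scion identity/coverage thresholds; only reads failing that
#' are rescued against the rootstock reference, where candidates must reach
#' \code{rootstockIdentityMin} (0.95 by default, the mobile-mRNA identity
#' rule) over \code{rootstockCoverageMin} of the read. A rootstock gene seen
#' with at least \code{homograftDetectionThreshold} candidate reads in any
#' homograft control sample is excluded as a homology-driven false positive.
#'
#' @slot scionIdentityMin,scionCoverageMin scion-stage thresholds.
#' @slot rootstockIdentityMin,rootstockCoverageMin rescue-stage thresholds.
#' @slot homograftDetectionThreshold reads in any homograft sample that
#'   disqualify a gene.
#' @slot seedK k-mer size used for alignment seeding.
#' @slot band half-width of the banded global alignment.
#' @slot matchScore,mismatchScore,gapScore alignment scores.
#' @exportClass ClassificationParams
setClass("ClassificationParams",
    representation(
        scionIdentityMin = "numeric", scionCoverageMin = "numeric",
        rootstockIdentityMin = "numeric", rootstockCoverageMin = "numeric",
        homograftDetectionThreshold = "numeric",
        seedK = "numeric", band = "numeric",
        matchScore = "numeric", mismatchScore = "numeric",
        gapScore = "numeric"
    )
)

setValidity("ClassificationParams", function(object) {
    fr <- c(object@scionIdentityMin, object@scionCoverageMin,
            object@rootstockIdentityMin, object@rootstockCoverageMin)
    if (any(fr < 0 | fr > 1))
        return("identity/coverage thresholds must be fractions in [0, 1]")
    if (object@homograftDetectionThreshold < 0)
        return("homograftDetectionThreshold must be >= 0")
    if (object@seedK < 4 || object@seedK > 31)
        return("seedK must be in [4, 31]")
    TRUE
})

#' @rdname ClassificationParams-class
#' @param scionIdentityMin,scionCoverageMin,rootstockIdentityMin,rootstockCoverageMin,homograftDetectionThreshold,seedK,band,matchScore,mismatchScore,gapScore
#'   see slot descriptions.
#' @return A \linkS4class{ClassificationParams} object.
#' @export
classificationParams <- function(scionIdentityMin = 0.90,
                                 scionCoverageMin = 0.90,
                                 rootstockIdentityMin = 0.95,
                                 rootstockCoverageMin = 0.80,
                                 homograftDetectionThreshold = 1,
                                 seedK = 15, band = 3,
                                 matchScore = 1, mismatchScore = -1,
                                 gapScore = -2) {
    new("ClassificationParams",
        scionIdentityMin = scionIdentityMin,
        scionCoverageMin = scionCoverageMin,
        rootstockIdentityMin = rootstockIdentityMin,
        rootstockCoverageMin = rootstockCoverageMin,
        homograftDetectionThreshold = homograftDetectionThreshold,
        seedK = seedK, band = band, matchScore = matchScore,
        mismatchScore = mismatchScore, gapScore = gapScore)
}

#' An RNA secondary structure in dot-bracket notation
#'
#' @slot sequence RNA sequence over A, C, G, U.
#' @slot structure balanced dot-bracket string of the same length.
#' @slot pairs two-column matrix of 1-based pair indices (i < j).
#' @exportClass DotBracketStructure
setClass("DotBracketStructure",
    representation(sequence = "character", structure = "character",
                   pairs = "matrix"))

setValidity("DotBracketStructure", function(object) {
    s <- object@sequence; db <- object@structure
    if (nchar(s) != nchar(db))
        return("sequence and structure lengths differ")
    ch <- strsplit(db, "")[[1]]
    if (!all(ch %in% c("(", ")", ".")))
        return("structure may contain only '(', ')' and '.'")
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (any(depth < 0) || (length(depth) && depth[length(depth)] != 0))
        return("unbalanced dot-bracket string")
    sv <- strsplit(toupper(chartr("T", "U", s)), "")[[1]]
    if (!all(sv %in% c("A", "C", "G", "U")))
        return("sequence must be over A, C, G, U/T")
    if (nrow(object@pairs)) {
        i <- object@pairs[, 1]; j <- object@pairs[, 2]
        if (any(i >= j)) return("pairs must have i < j")
        pp <- paste0(sv[i], sv[j])
        ok <- pp %in% c("AU", "UA", "GC", "CG", "GU", "UG")
        if (!all(ok))
            return(sprintf("non-canonical pair at (%d, %d)",
                           i[!ok][1], j[!ok][1]))
    }
    TRUE
})

setMethod("show", "DotBracketStructure", function(object) {
    n <- nchar(object@sequence)
    cat("DotBracketStructure (", n, " nt, ", nrow(object@pairs),
        " pairs)\n", sep = "")
    if (n <= 80) {
        cat(" ", object@sequence, "\n ", object@structure, "\n", sep = "")
    } else {
        cat(" ", substr(object@sequence, 1, 77), "...\n ",
            substr(object@structure, 1, 77), "...\n", sep = "")
    }
})

#' Loop census of a secondary structure
#'
#' Counts of the standard loop taxonomy obtained by traversing the structure
#' tree: hairpin loops (a pair enclosing no pair), stacks, bulges and
#' internal loops (a pair enclosing exactly one pair, with zero, one-sided or
#' two-sided unpaired bases), multibranch loops (a pair enclosing two or more
#' pairs) and the external loop (bases outside all pairs, counted once).
#'
#' @slot nExternal,nHairpin,nInternal,nBulge,nMultibranch,nStacks counts.
#' @exportClass LoopCensus
setClass("LoopCensus",
    representation(nExternal = "integer", nHairpin = "integer",
                   nInternal = "integer", nBulge = "integer",
                   nMultibranch = "integer", nStacks = "integer"))

setMethod("show", "LoopCensus", function(object) {
    cat("LoopCensus: hairpin", object@nHairpin, "| internal",
        object@nInternal, "| bulge", object@nBulge, "| multibranch",
        object@nMultibranch, "| stacks", object@nStacks, "| external",
        object@nExternal, "\n")
})

#' Base-pair probabilities and positional entropy of an RNA
#'
#' The thermodynamic ensemble of all pseudoknot-free structures under the
#' simplified constant-energy-per-pair model. For every position,
#' \code{unpaired[i] + sum_j P[i, j] = 1}; the positional entropy (nats)
#' is the Shannon entropy of the position's pairing state.
#'
#' @slot sequence the folded RNA sequence.
#' @slot P symmetric base-pair probability matrix.
#' @slot unpaired per-base probability of being unpaired.
#' @slot entropy per-base positional entropy in nats.
#' @exportClass PairProbabilityProfile
setClass("PairProbabilityProfile",
    representation(sequence = "character", P = "matrix",
                   unpaired = "numeric", entropy = "numeric"))

setValidity("PairProbabilityProfile", function(object) {
    n <- nchar(object@sequence)
    if (!all(dim(object@P) == c(n, n))) return("P must be n x n")
    tot <- object@unpaired + rowSums(object@P)
    if (any(abs(tot - 1) > 1e-6))
        return("unpaired[i] + sum_j P[i, j] must equal 1")
    if (any(object@entropy < -1e-12)) return("entropy must be >= 0")
    TRUE
})

setMethod("show", "PairProbabilityProfile", function(object) {
    cat("PairProbabilityProfile (", nchar(object@sequence), " nt), mean",
        " entropy ", round(mean(object@entropy), 3), " nats\n", sep = "")
})

#' Fuzzy c-means clustering result
#'
#' @slot membership genes x clusters membership matrix (rows sum to 1).
#' @slot centers clusters x samples center profiles.
#' @slot hardAssignment argmax cluster per gene.
#' @slot objective value of the fuzzy objective at each iteration
#'   (non-increasing).
#' @slot fuzzifier the fuzzifier m used.
#' @exportClass FuzzyClustering
setClass("FuzzyClustering",
    representation(membership = "matrix", centers = "matrix",
                   hardAssignment = "integer", objective = "numeric",
                   fuzzifier = "numeric"))

setValidity("FuzzyClustering", function(object) {
    rs <- rowSums(object@membership)
    if (any(abs(rs - 1) > 1e-6)) return("memberships must row-sum to 1")
    if (any(object@membership < -1e-12 | object@membership > 1 + 1e-12))
        return("memberships must lie in [0, 1]")
    TRUE
})

setMethod("show", "FuzzyClustering", function(object) {
    cat("FuzzyClustering:", nrow(object@membership), "genes,",
        ncol(object@membership), "clusters (m =", object@fuzzifier, ")\n")
    print(table(cluster = object@hardAssignment))
})
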