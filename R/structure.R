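## RNA secondary structure at desk scale: maximum base pairing (Nussinov),
## a McCaskill-style partition function over a constant energy per pair,
## loop decomposition and mountain profiles. The energy model is
## deliberately simple (every allowed pair contributes the same energy;
## AU/GC/GU pairing, a minimum hairpin of 3 unpaired bases), which keeps
## the ensemble exactly enumerable at small lengths for verification while
## preserving the loop taxonomy and entropy machinery.

.norm_rna <- function(sequence) {
    s <- toupper(chartr("tT", "uU", sequence))
    bad <- regexpr("[^ACGU]", s)
    if (bad > 0)
        stop("invalid character at position ", bad)
    s
}

.pairs_from_db <- function(db) {
    ch <- strsplit(db, "")[[1]]
    open <- integer(0)
    out <- matrix(0L, nrow = 0, ncol = 2)
    pr <- list()
    for (i in seq_along(ch)) {
        if (ch[i] == "(") open <- c(open, i)
        else if (ch[i] == ")") {
            if (!length(open)) stop("unbalanced structure")
            pr[[length(pr) + 1L]] <- c(open[length(open)], i)
            open <- open[-length(open)]
        }
    }
    if (length(open)) stop("unbalanced structure")
    if (length(pr)) do.call(rbind, pr) else out
}

#' Construct a dot-bracket structure object
#'
#' @param sequence RNA (or DNA; T is read as U) sequence.
#' @param structure dot-bracket string of equal length.
#' @return A validated \linkS4class{DotBracketStructure}.
#' @examples
#' dotBracket("GGGAAACCC", "(((...)))")
#' @export
dotBracket <- function(sequence, structure) {
    sequence <- .norm_rna(sequence)
    new("DotBracketStructure", sequence = sequence, structure = structure,
        pairs = .pairs_from_db(structure))
}

#' Maximum base-pairing fold (Nussinov)
#'
#' Dynamic program maximizing the number of allowed pairs (AU, GC, GU and
#' reverses) subject to a minimum hairpin of \code{min_hairpin} unpaired
#' bases, with deterministic traceback (prefer leaving a base unpaired,
#' then the smallest partner index).
#'
#' @param sequence RNA sequence (T accepted and read as U).
#' @param min_hairpin minimum unpaired bases enclosed by a hairpin pair.
#' @return A \linkS4class{DotBracketStructure}.
#' @examples
#' nussinovFold("GGGAAACCC")
#' @export
nussinovFold <- function(sequence, min_hairpin = 3) {
    sequence <- .norm_rna(sequence)
    if (nchar(sequence) == 0) stop("empty sequence")
    r <- .nussinov_cpp(sequence, as.integer(min_hairpin))
    pairs <- r$pairs
    if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    new("DotBracketStructure", sequence = sequence,
        structure = r$structure, pairs = pairs)
}

#' Base-pair probabilities, unpaired probabilities and positional entropy
#'
#' Inside/outside recursions over Boltzmann weights exp(-E/kT) with a
#' constant energy E per allowed pair give the ensemble probability
#' P[i, j] that (i, j) is paired; unpaired[i] = 1 - sum_j P[i, j]; the
#' positional entropy (nats) is
#' -sum_j P[i, j] log P[i, j] - unpaired[i] log unpaired[i].
#'
#' @param sequence RNA sequence (T read as U).
#' @param pair_energy energy per pair (negative stabilizes pairing).
#' @param kT thermal energy; as kT -> 0 the ensemble concentrates on
#'   maximum-pairing structures.
#' @param min_hairpin minimum hairpin size.
#' @param max_length guard against partition-function overflow; longer
#'   inputs are rejected.
#' @return A \linkS4class{PairProbabilityProfile}.
#' @examples
#' p <- pairProbabilities("GGGAAACCC")
#' round(p@unpaired, 3)
#' @export
pairProbabilities <- function(sequence, pair_energy = -1, kT = 1,
                              min_hairpin = 3, max_length = 2000) {
    sequence <- .norm_rna(sequence)
    n <- nchar(sequence)
    if (n == 0) stop("empty sequence")
    if (n > max_length)
        stop("sequence longer than ", max_length,
             " nt risks partition-function overflow; fold a subsequence ",
             "or raise kT")
    r <- .mccaskill_cpp(sequence, pair_energy, kT, as.integer(min_hairpin))
    P <- r$P
    unpaired <- pmax(1 - rowSums(P), 0)
    plogp <- function(p) ifelse(p > 0, p * log(p), 0)
    entropy <- -rowSums(plogp(P)) - plogp(unpaired)
    entropy[entropy < 0] <- 0       # clamp -0 from roundoff
    new("PairProbabilityProfile", sequence = sequence, P = P,
        unpaired = unpaired, entropy = entropy)
}

#' Loop census of a dot-bracket structure
#'
#' Standard loop decomposition by structure-tree traversal: a pair
#' enclosing no pair closes a hairpin; a pair enclosing exactly one pair
#' closes a stack (no unpaired bases), a bulge (unpaired on one side) or an
#' internal loop (unpaired on both sides); a pair enclosing two or more
#' pairs closes a multibranch loop. Bases outside all pairs form one
#' external loop, counted once if any exist. Counts depend only on the
#' bracket string.
#'
#' @param x a \linkS4class{DotBracketStructure}, or a dot-bracket string.
#' @return A \linkS4class{LoopCensus}.
#' @examples
#' loopCounts(decomposeLoops("((..((...))..))"))
#' @export
decomposeLoops <- function(x) {
    db <- if (is(x, "DotBracketStructure")) x@structure else x
    ch <- strsplit(db, "")[[1]]
    if (!all(ch %in% c("(", ")", ".")))
        stop("structure may contain only '(', ')' and '.'")
    pairs <- .pairs_from_db(db)
    n <- length(ch)
    partner <- integer(n)
    if (nrow(pairs)) {
        partner[pairs[, 1]] <- pairs[, 2]
        partner[pairs[, 2]] <- pairs[, 1]
    }
    n_hairpin <- n_internal <- n_bulge <- n_multi <- n_stack <- 0L
    ## children of the pair (i, j): maximal pairs directly enclosed
    children <- function(i, j) {
        out <- list()
        k <- i + 1L
        while (k < j) {
            if (partner[k] > k) {
                out[[length(out) + 1L]] <- c(k, partner[k])
                k <- partner[k] + 1L
            } else k <- k + 1L
        }
        out
    }
    if (nrow(pairs)) {
        for (p in seq_len(nrow(pairs))) {
            i <- pairs[p, 1]; j <- pairs[p, 2]
            kids <- children(i, j)
            if (length(kids) == 0) {
                n_hairpin <- n_hairpin + 1L
            } else if (length(kids) == 1) {
                ci <- kids[[1]][1]; cj <- kids[[1]][2]
                left <- ci - i - 1L
                right <- j - cj - 1L
                if (left == 0 && right == 0) n_stack <- n_stack + 1L
                else if (left > 0 && right > 0) n_internal <- n_internal + 1L
                else n_bulge <- n_bulge + 1L
            } else {
                n_multi <- n_multi + 1L
            }
        }
    }
    paired <- partner > 0
    ## positions not enclosed by any pair
    depth <- cumsum((ch == "(")) - cumsum(c(0, (ch == ")")[-n]))
    external_any <- any(!paired & depth == 0)
    new("LoopCensus",
        nExternal = as.integer(external_any),
        nHairpin = n_hairpin, nInternal = n_internal, nBulge = n_bulge,
        nMultibranch = n_multi, nStacks = n_stack)
}

#' @rdname decomposeLoops
#' @param census a \linkS4class{LoopCensus}.
#' @return \code{loopCounts}: a named integer vector of the census.
#' @export
loopCounts <- function(census) {
    c(external = census@nExternal, hairpin = census@nHairpin,
      internal = census@nInternal, bulge = census@nBulge,
      multibranch = census@nMultibranch, stacks = census@nStacks)
}

#' Mountain profile of a structure and its ensemble
#'
#' For the single structure, the height at position k is the number of
#' pairs (i, j) with i <= k < j; for the ensemble, each pair contributes
#' its probability P[i, j]; the centroid is the structure containing
#' exactly the pairs with P[i, j] > 0.5.
#'
#' @param structure a \linkS4class{DotBracketStructure} (or NULL).
#' @param profile a \linkS4class{PairProbabilityProfile} (or NULL).
#' @return A data.frame with position and the available height columns
#'   (\code{mfe}, \code{ensemble}, \code{centroid}).
#' @examples
#' mountainProfile(dotBracket("GGGAAACCC", "(((...)))"))
#' @export
mountainProfile <- function(structure = NULL, profile = NULL) {
    if (is.null(structure) && is.null(profile))
        stop("supply a structure and/or a probability profile")
    heights_from_pairs <- function(pairs, n) {
        h <- numeric(n)
        if (nrow(pairs))
            for (p in seq_len(nrow(pairs))) {
                i <- pairs[p, 1]; j <- pairs[p, 2]
                h[i:(j - 1)] <- h[i:(j - 1)] + 1
            }
        h
    }
    out <- NULL
    if (!is.null(structure)) {
        n <- nchar(structure@sequence)
        out <- data.frame(position = seq_len(n),
                          mfe = heights_from_pairs(structure@pairs, n))
    }
    if (!is.null(profile)) {
        n <- nchar(profile@sequence)
        if (is.null(out)) out <- data.frame(position = seq_len(n))
        P <- profile@P
        ens <- numeric(n)
        idx <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
        if (nrow(idx))
            for (r in seq_len(nrow(idx))) {
                i <- idx[r, 1]; j <- idx[r, 2]
                ens[i:(j - 1)] <- ens[i:(j - 1)] + P[i, j]
            }
        out$ensemble <- ens
        cent <- which(upper.tri(P) & P > 0.5, arr.ind = TRUE)
        out$centroid <- heights_from_pairs(cent, n)
    }
    out
}
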