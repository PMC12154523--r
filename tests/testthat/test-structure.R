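test_that("unpairable sequences fold open", {
    s <- nussinovFold("AAAAAA")
    expect_equal(s@structure, "......")
    expect_equal(nrow(s@pairs), 0)
})

test_that("a perfect stem folds to its maximum pairing", {
    s <- nussinovFold("GGGAAACCC", min_hairpin = 3)
    expect_equal(s@structure, "(((...)))")
    expect_equal(nrow(s@pairs), 3)
    # brute-force enumeration confirms 3 is the maximum
    best <- max(vapply(enumerate_structures("GGGAAACCC"), nrow, 0L))
    expect_equal(nrow(s@pairs), best)
})

test_that("DP pair counts equal the brute-force maximum for short sequences", {
    set.seed(71)
    for (i in 1:40) {
        seq <- random_rna(sample(5:12, 1))
        got <- nrow(nussinovFold(seq)@pairs)
        best <- max(vapply(enumerate_structures(seq), nrow, 0L))
        expect_equal(got, best, info = seq)
    }
})

test_that("invalid characters are rejected with their position", {
    expect_error(nussinovFold("ACGXU"), "position 4")
})

test_that("pair probabilities conserve probability and match enumeration", {
    set.seed(72)
    for (i in 1:15) {
        seq <- random_rna(sample(6:12, 1))
        prof <- pairProbabilities(seq)
        expect_true(all(abs(prof@unpaired + rowSums(prof@P) - 1) < 1e-9))
        expect_equal(prof@P, ensemble_oracle(seq), tolerance = 1e-9,
                     info = seq)
    }
})

test_that("single-structure ensembles have zero entropy", {
    prof <- pairProbabilities("AAAA")
    expect_true(all(prof@unpaired == 1))
    expect_true(all(prof@entropy == 0))
    # too short to satisfy the hairpin constraint
    prof2 <- pairProbabilities("GC", min_hairpin = 3)
    expect_true(all(prof2@unpaired == 1))
})

test_that("low temperature concentrates the ensemble on the maximum pairing", {
    seq <- "GGGAAACCC"
    prof <- pairProbabilities(seq, pair_energy = -1, kT = 0.05)
    mfe <- nussinovFold(seq)
    for (r in seq_len(nrow(mfe@pairs))) {
        expect_gt(prof@P[mfe@pairs[r, 1], mfe@pairs[r, 2]], 0.99)
    }
    # entropy vanishes where the pairing state is certain
    expect_true(all(prof@entropy[unique(as.vector(mfe@pairs))] < 0.1))
})

test_that("loop decomposition matches hand-derived censuses", {
    expect_equal(loopCounts(decomposeLoops("((((....))))")),
                 c(external = 0, hairpin = 1, internal = 0, bulge = 0,
                   multibranch = 0, stacks = 3))
    expect_equal(loopCounts(decomposeLoops("((..((...))..))")),
                 c(external = 0, hairpin = 1, internal = 1, bulge = 0,
                   multibranch = 0, stacks = 2))
    expect_equal(loopCounts(decomposeLoops("(...).(...)")),
                 c(external = 1, hairpin = 2, internal = 0, bulge = 0,
                   multibranch = 0, stacks = 0))
    expect_equal(loopCounts(decomposeLoops("((.((...))((...)).))")),
                 c(external = 0, hairpin = 2, internal = 0, bulge = 0,
                   multibranch = 1, stacks = 3))
    expect_equal(loopCounts(decomposeLoops("((((...).)))")),
                 c(external = 0, hairpin = 1, internal = 0, bulge = 1,
                   multibranch = 0, stacks = 2))
    expect_error(decomposeLoops("(()"), "unbalanced")
})

test_that("loop counts depend only on the bracket string", {
    db <- "((..((...))..))"
    a <- decomposeLoops(dotBracket("GGAAGGAAACCAACC", db))
    b <- decomposeLoops(db)
    expect_equal(loopCounts(a), loopCounts(b))
})

test_that("mountain heights follow the pair-counting convention", {
    expect_true(all(mountainProfile(dotBracket("AAAAAA", "......"))$mfe == 0))
    mp <- mountainProfile(dotBracket("GGAAACC", "((...))"))
    expect_equal(mp$mfe, c(1, 2, 2, 2, 2, 1, 0))
    prof <- pairProbabilities("GGGAAACCC")
    em <- mountainProfile(profile = prof)
    expect_true(all(em$ensemble <= nchar("GGGAAACCC") / 2))
    expect_true(all(em$ensemble >= 0))
})
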