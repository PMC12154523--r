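test_that("FPKM follows its closed form and scale invariance", {
    expect_equal(computeFPKM(matrix(1000), 1000, 1e6)[1, 1], 1000)
    expect_equal(computeFPKM(matrix(0), 500, 1e6)[1, 1], 0)
    counts <- matrix(rpois(20, 40), 4, 5,
                     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    lens <- c(g1 = 500, g2 = 1000, g3 = 1500, g4 = 2000)
    libs <- seq(1e6, 3e6, length.out = 5)
    f1 <- computeFPKM(counts, lens, libs)
    f2 <- computeFPKM(2 * counts, lens, 2 * libs)
    expect_equal(f1, f2)
    expect_error(computeFPKM(matrix(1), 0, 1e6), "positive")
})

test_that("identical groups give zero fold changes and no calls", {
    counts <- matrix(rpois(30, 60), 5, 6,
                     dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    counts <- counts[, c(1:3, 1:3)]
    colnames(counts) <- paste0("s", 1:6)
    de <- callDifferential(counts, rep(1000, 5), rep(1e6, 6), 1:3, 4:6)
    expect_true(all(de$log2_fc == 0))
    expect_false(any(de$is_significant))
})

test_that("swapping groups negates fold changes and keeps p-values", {
    set.seed(8)
    counts <- matrix(rpois(60, 80), 10, 6,
                     dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    libs <- c(1e6, 1.2e6, 0.8e6, 1.1e6, 0.9e6, 1e6)
    ab <- callDifferential(counts, rep(1000, 10), libs, 1:3, 4:6)
    ba <- callDifferential(counts, rep(1000, 10), libs, 4:6, 1:3)
    expect_equal(ab$log2_fc, -ba$log2_fc)
    expect_equal(ab$p_value, ba$p_value)
})

test_that("the exact binomial p matches brute-force tail summation", {
    expect_equal(callDifferential(
        matrix(c(40, 10), 1, 2, dimnames = list("g", c("a", "b"))),
        1000, c(1e6, 1e6), 1, 2)$p_value,
        binom_two_sided_oracle(40, 50, 0.5), tolerance = 1e-12)
    set.seed(77)
    for (i in 1:30) {
        n <- sample(1:200, 1); x <- sample(0:n, 1)
        p0 <- runif(1, 0.2, 0.8)
        lib_a <- 1e6 * p0 / (1 - p0); lib_b <- 1e6
        cm <- matrix(c(x, n - x), 1, 2, dimnames = list("g", c("a", "b")))
        got <- callDifferential(cm, 1000, c(lib_a, lib_b), 1, 2)$p_value
        expect_equal(got, binom_two_sided_oracle(x, n, p0),
                     tolerance = 1e-9, info = paste("case", i))
    }
})

test_that("BH adjustment equals the brute-force step-up", {
    expect_equal(benjaminiHochberg(0.03), 0.03)
    expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)),
                 rep(0.04, 4))
    expect_equal(benjaminiHochberg(rep(0.2, 7)), rep(0.2, 7))
    set.seed(55)
    for (i in 1:50) {
        p <- runif(sample(1:50, 1))
        expect_equal(benjaminiHochberg(p), bh_stepup_oracle(p),
                     info = paste("case", i))
    }
    expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted fold changes are detected with controlled FDR", {
    sens <- numeric(0); fp <- 0L; calls <- 0L
    for (s in 1:8) {
        set.seed(400 + s)
        mu <- rgamma(200, shape = 2, rate = 0.002)
        counts <- matrix(rpois(1200, rep(mu, 6)), 200, 6,
                         dimnames = list(sprintf("g%03d", 1:200),
                                         sprintf("s%d", 1:6)))
        counts[1:10, 1:3] <- rpois(30, 4 * mu[1:10])
        de <- callDifferential(counts, rep(1000, 200), rep(1e6, 6), 1:3, 4:6)
        hits <- which(de$is_significant)
        sens <- c(sens, mean(1:10 %in% hits))
        fp <- fp + sum(hits > 10); calls <- calls + length(hits)
    }
    expect_gte(mean(sens), 0.8)
    expect_lte(fp / max(1L, calls), 0.1)
})

test_that("2^-ddCt arithmetic", {
    expect_equal(deltaDeltaCt(20, 18, 22, 20), 1.0)
    expect_equal(deltaDeltaCt(25, 20, 24, 20), 0.5)
    expect_equal(deltaDeltaCt(23, 20, 24, 20), 2.0)
})
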