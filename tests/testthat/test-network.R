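test_that("Spearman correlation basics and oracle agreement", {
    set.seed(81)
    x <- rnorm(10)
    expect_equal(spearmanRho(x, x), 1.0)
    expect_equal(spearmanRho(c(1, 2, 3, 4), c(8, 6, 4, 2)), -1.0)
    expect_warning(r <- spearmanRho(rep(2, 5), 1:5), "constant")
    expect_true(is.na(r))
    expect_error(spearmanRho(1:2, 1:2), "at least 3")
    for (i in 1:40) {
        n <- sample(3:8, 1)
        a <- sample(1:4, n, replace = TRUE)   # heavy ties
        b <- rnorm(n)
        if (sd(a) == 0) next
        expect_equal(spearmanRho(a, b), spearman_oracle(a, b),
                     tolerance = 1e-12, info = paste("case", i))
    }
})

test_that("Spearman is symmetric and monotone-invariant", {
    set.seed(82)
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(spearmanRho(x, y), spearmanRho(y, x))
    expect_equal(spearmanRho(exp(3 * x), y), spearmanRho(x, y))
    expect_equal(spearmanRho(x, -y), -spearmanRho(x, y))
})

test_that("tie-free length-4 profiles attain the expected rho values", {
    library(utils)
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
    rhos <- sort(unique(round(apply(perms, 1, function(r)
        spearmanRho(as.numeric(r), 1:4)), 10)))
    expect_equal(rhos, seq(-1, 1, by = 0.2))
})

test_that("network edges respect the threshold and canonical order", {
    profiles <- rbind(
        rnaA = c(1, 2, 3, 4, 5, 6),
        mobB = c(2, 4, 6, 8, 10, 12),    # rho 1 with rnaA
        metC = c(6, 5, 4, 3, 2, 1))      # rho -1 with both
    net <- buildNetwork(profiles, c("rna", "mobile_rna", "metabolite"),
                        rho_min = 0.9)
    expect_equal(nrow(net$edges), 3)
    expect_true(all(net$edges$node_a < net$edges$node_b))
    e <- net$edges[net$edges$node_a == "mobB" & net$edges$node_b == "rnaA", ]
    expect_equal(e$rho, 1.0)
    expect_equal(e$sign, "+")
    # unreachable threshold empties the network
    empty <- buildNetwork(profiles, c("rna", "mobile_rna", "metabolite"),
                          rho_min = 1.01)
    expect_equal(nrow(empty$edges), 0)
})

test_that("edge count is non-increasing in the threshold", {
    set.seed(83)
    profiles <- matrix(rnorm(10 * 8), 10, 8,
                       dimnames = list(paste0("n", 1:10), NULL))
    types <- rep("rna", 10)
    counts <- vapply(c(0.2, 0.5, 0.8, 0.95), function(t)
        nrow(buildNetwork(profiles, types, t)$edges), 0)
    expect_true(all(diff(counts) <= 0))
})

test_that("a planted metabolite coupling is recovered as an edge", {
    hits <- 0L; spurious <- 0L
    for (s in 1:20) {
        set.seed(900 + s)
        expr <- matrix(rnorm(12), 1, 12, dimnames = list("gene1", NULL))
        met <- simulateMetabolites(expr,
            data.frame(gene = "gene1", metabolite = "met1", rho = 1),
            noise_sd = 0, seed = s, n_background = 3)
        profiles <- rbind(expr, met)
        net <- buildNetwork(profiles,
            c("mobile_rna", rep("metabolite", 4)), rho_min = 0.9)
        e <- net$edges
        hits <- hits + any(e$node_a == "gene1" & e$node_b == "met1" |
                           e$node_a == "met1" & e$node_b == "gene1")
        spurious <- spurious + sum(grepl("bgmet", e$node_a) |
                                   grepl("bgmet", e$node_b))
    }
    expect_equal(hits, 20L)
    expect_lte(spurious, 2L)
})

test_that("pathway filtering keeps only doubly tagged edges", {
    profiles <- rbind(
        g1 = c(1, 2, 3, 4, 5, 6), g2 = c(1.1, 2, 3, 4, 5, 6.2),
        m1 = c(6, 5, 4, 3, 2, 1), x1 = c(2, 4, 6, 8, 10, 12))
    types <- c("rna", "mobile_rna", "metabolite", "rna")
    net <- buildNetwork(profiles, types, rho_min = 0.9)
    memb <- data.frame(node = c("g1", "g2", "m1"),
                       pathway = "photosynthesis")
    sub <- pathwaySubnetwork(net, memb, "photosynthesis")
    expect_true(all(sub$edges$node_a %in% memb$node &
                    sub$edges$node_b %in% memb$node))
    expect_false("x1" %in% sub$nodes$id)
    # all nodes tagged leaves the network unchanged
    all_m <- data.frame(node = rownames(profiles), pathway = "p")
    expect_equal(pathwaySubnetwork(net, all_m, "p")$edges, net$edges)
    # no nodes tagged empties it; unknown tags are an error
    none <- pathwaySubnetwork(net, memb, character(0))
    expect_equal(nrow(none$edges), 0)
    expect_error(pathwaySubnetwork(net, memb, "glycolysis"),
                 "unknown pathway")
})

test_that("igraph conversion and GraphML export round-trip node types", {
    profiles <- rbind(a = 1:6, b = c(2, 4, 6, 8, 10, 12), c = 6:1)
    net <- buildNetwork(profiles, c("rna", "mobile_rna", "metabolite"), 0.9)
    g <- asIgraph(net)
    expect_equal(igraph::vcount(g), 3)
    expect_equal(igraph::ecount(g), nrow(net$edges))
    f <- tempfile(fileext = ".graphml")
    writeGraphML(net, f)
    g2 <- igraph::read_graph(f, format = "graphml")
    expect_equal(igraph::ecount(g2), nrow(net$edges))
    expect_setequal(igraph::V(g2)$type, c("rna", "mobile_rna", "metabolite"))
})
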