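test_that("ortholog pairs hit the identity target and the pair count", {
    cfg <- simulationConfig(nGenes = 12, geneLengthRange = c(900, 1100),
                            orthologIdentity = 0.85, nMobile = 2,
                            readsPerSample = 100, seed = 42)
    gs <- generateGeneSets(cfg)
    expect_length(gs$scion, 12)
    expect_length(gs$rootstock, 12)
    expect_equal(nrow(gs$orthologMap), 12)
    for (i in seq_len(12)) {
        aln <- nwAlign(as.character(gs$scion[[i]]),
                       as.character(gs$rootstock[[i]]))
        expect_gte(aln$identity, 0.83)
        expect_lte(aln$identity, 0.87)
    }
})

test_that("zero divergence yields identical ortholog copies", {
    cfg <- simulationConfig(nGenes = 4, geneLengthRange = c(100, 150),
                            orthologIdentity = 1, nMobile = 1,
                            readsPerSample = 10, readLength = 50, seed = 5)
    gs <- generateGeneSets(cfg)
    expect_identical(unname(as.character(gs$scion)),
                     unname(as.character(gs$rootstock)))
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(orthologIdentity = 0), "orthologIdentity")
    expect_error(simulationConfig(mobilityNear = 0.01, mobilityFar = 0.02),
                 "mobilityFar")
    expect_error(simulationConfig(geneLengthRange = c(10, 15)), "20 nt")
    expect_error(simulationConfig(nGenes = 0), "positive")
})

test_that("simulation is byte-identical under a fixed seed", {
    cfg <- tiny_config(seed = 7, readsPerSample = 300)
    s1 <- simulateGraftExperiment(cfg)
    s2 <- simulateGraftExperiment(cfg)
    expect_identical(as.character(s1@scion), as.character(s2@scion))
    expect_identical(s1@reads, s2@reads)
    d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
    writeSimulation(s1, d1); writeSimulation(s2, d2)
    for (f in grep("\\.(fa|fastq)$", list.files(d1), value = TRUE)) {
        expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                         readBin(file.path(d2, f), "raw", 1e7))
    }
})

test_that("noiseless homograft reads are exact transcript substrings", {
    cfg <- tiny_config(seed = 3, errorRate = 0, readsPerSample = 200)
    sim <- simulateGraftExperiment(cfg)
    rd <- sampleReads(sim, "XG_1")
    refs <- as.character(scionReference(sim))
    for (i in seq_len(50)) {
        gene <- rd$origin_gene[i]
        seq <- rd$seq[i]
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq)))
        expect_true(grepl(seq, refs[gene], fixed = TRUE) ||
                    grepl(rc, refs[gene], fixed = TRUE))
    }
})

test_that("true rootstock-origin counts follow the mobility factor", {
    cfg <- simulationConfig(nGenes = 40, geneLengthRange = c(300, 500),
                            nMobile = 8, mobilityNear = 0.02,
                            mobilityFar = 0.004, readsPerSample = 50000,
                            nReplicates = 1, seed = 21)
    sim <- simulateGraftExperiment(cfg)
    truth <- groundTruth(sim)
    rs_genes <- names(rootstockReference(sim))
    n_near <- sum(truth$origin_counts[rs_genes, "YJ_1"])
    sdev <- sqrt(50000 * 0.02 * 0.98)
    expect_lt(abs(n_near - 1000), 3 * sdev)
    # per-sample origin counts account for every read
    expect_true(all(colSums(truth$origin_counts) == 50000))
    # homograft samples carry no rootstock-origin reads
    homo <- sampleSheet(sim)$sample_id[sampleSheet(sim)$graft_type == "homo"]
    expect_true(all(truth$origin_counts[rs_genes, homo] == 0))
})

test_that("paired-end mates agree in count and name", {
    cfg <- tiny_config(seed = 9, readsPerSample = 100, paired = TRUE)
    sim <- simulateGraftExperiment(cfg)
    rd <- sampleReads(sim, "YJ_1")
    expect_length(rd$seq2, length(rd$seq))
    expect_length(rd$id, length(rd$seq))
    # mate 2 is the fragment's reverse complement
    expect_identical(
        as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(rd$seq2))), rd$seq)
})

test_that("metabolite coupling achieves exact rank correlation without noise", {
    expr <- matrix(c(1, 3, 2, 8, 5, 13, 21, 34, 4, 4, 4, 4),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gB"), NULL))
    expr <- rbind(expr, gC = c(5, 1, 4, 2, 8, 6))
    up <- simulateMetabolites(expr[, 1:6],
        data.frame(gene = "gA", metabolite = "m1", rho = 1), 0, seed = 2)
    expect_equal(spearmanRho(up["m1", ], expr["gA", 1:6]), 1.0)
    dn <- simulateMetabolites(expr[, 1:6],
        data.frame(gene = "gC", metabolite = "m2", rho = -1), 0, seed = 2)
    expect_equal(spearmanRho(dn["m2", ], expr["gC", 1:6]), -1.0)
    expect_error(simulateMetabolites(expr[, 1:2, drop = FALSE],
        data.frame(gene = "gA", metabolite = "m", rho = 1), 0), "4 samples")
})

test_that("calibrated noise gives the target mean correlation magnitude", {
    set.seed(1)
    expr <- matrix(rnorm(12), 1, 12, dimnames = list("g", NULL))
    rhos <- vapply(seq_len(200), function(s) {
        m <- simulateMetabolites(expr,
            data.frame(gene = "g", metabolite = "m", rho = 0.8),
            noise_sd = noiseForTargetRho(0.8), seed = s)
        spearmanRho(m["m", ], expr["g", ])
    }, numeric(1))
    expect_lt(abs(mean(rhos) - 0.8), 0.15)
    expect_true(all(tabulate(sign(rhos) + 2, 3)[1] < 10)) # sign flips rare
})
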