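test_that("read accounting conserves reads in every sample", {
    sim <- simulateGraftExperiment(tiny_config(seed = 31,
                                               readsPerSample = 800))
    se <- classifyExperiment(sim)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    expect_true(all(cd$scion_mapped + cd$unmapped == cd$clean_reads))
    expect_true(all(cd$rootstock_mapped <= cd$unmapped))
    expect_true(all(cd$scion_mapped_rate >= 0 & cd$scion_mapped_rate <= 100))
    expect_true(all(cd$rootstock_mapped_rate >= 0 &
                    cd$rootstock_mapped_rate <= 100))
})

test_that("classification recovers planted mobile genes on a small design", {
    sim <- simulateGraftExperiment(tiny_config(seed = 3))
    se <- classifyExperiment(sim)
    sh <- subtractHomograft(se)
    stats <- recovery_stats(sh$mobile_genes,
                            groundTruth(sim)$mobile_gene_ids)
    expect_gte(stats["sensitivity"], 0.9)
    expect_gte(stats["precision"], 0.9)
})

test_that("raising the rescue identity threshold never grows the candidate set", {
    sim <- simulateGraftExperiment(tiny_config(seed = 32,
                                               readsPerSample = 1500,
                                               errorRate = 0.02))
    sets <- lapply(c(0.90, 0.95, 0.99), function(idmin) {
        se <- classifyExperiment(sim,
            params = classificationParams(rootstockIdentityMin = idmin))
        counts <- SummarizedExperiment::assay(se)
        rownames(counts)[rowSums(counts) > 0]
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("classification never reads provenance tags in read names", {
    sim <- simulateGraftExperiment(tiny_config(seed = 33,
                                               readsPerSample = 600))
    rd <- sampleReads(sim, "YJ_2")
    base <- classifySample(rd, scionReference(sim), rootstockReference(sim))
    shuffled <- rd
    set.seed(1)
    shuffled$id <- sample(shuffled$id)   # permute tags across reads
    perm <- classifySample(shuffled, scionReference(sim),
                           rootstockReference(sim))
    expect_identical(base$counts, perm$counts)
    expect_identical(base$accounting, perm$accounting)
})

test_that("reads identical to one scion gene all map to the scion", {
    set.seed(34)
    g <- random_dna(500)
    scion <- Biostrings::DNAStringSet(c(SCgene = g))
    root <- Biostrings::DNAStringSet(c(RSgene = random_dna(500)))
    reads <- list(id = sprintf("r%d", 1:50),
                  seq = vapply(sample(1:400, 50, replace = TRUE),
                               function(s) substr(g, s, s + 99), ""),
                  qual = rep(strrep("I", 100), 50))
    cl <- classifySample(reads, scion, root)
    expect_equal(cl$accounting$scion_mapped, 50)
    expect_equal(cl$accounting$unmapped, 0)
    expect_true(all(cl$counts == 0))
})

test_that("homograft subtraction removes genes seen in controls", {
    counts <- matrix(c(50, 50, 50, 50, 3, 0, 0, 0), nrow = 2, byrow = FALSE,
                     dimnames = list(c("RSa", "RSb"),
                                     c("YJ_1", "YJ_2", "XJ_1", "XJ_2")))
    cd <- S4Vectors::DataFrame(
        graft_type = c("hetero", "hetero", "homo", "homo"),
        row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(candidate_counts = counts), colData = cd)
    sh <- subtractHomograft(se, classificationParams(
        homograftDetectionThreshold = 1))
    expect_identical(sh$excluded, "RSa")
    expect_identical(sh$mobile_genes, "RSb")
    # a higher threshold tolerates the 3 control reads
    sh2 <- subtractHomograft(se, classificationParams(
        homograftDetectionThreshold = 5))
    expect_identical(sort(sh2$mobile_genes), c("RSa", "RSb"))
    # no homograft samples: pass-through with a warning
    se_h <- se[, 1:2]
    expect_warning(sh3 <- subtractHomograft(se_h), "no homograft")
    expect_identical(sort(sh3$mobile_genes), c("RSa", "RSb"))
})

test_that("mapped rate reproduces printed two-decimal rounding", {
    expect_identical(mappedRate(32064, 8828672), 0.36)
    expect_identical(mappedRate(495277, 16256512), 3.05)
    expect_identical(mappedRate(0, 1000), 0)
    expect_identical(mappedRate(125, 100000), 0.13)  # half away from zero
    expect_error(mappedRate(1, 0), "positive")
    expect_error(mappedRate(5, 4), "mapped")
})

test_that("empty read sets yield zero accounting", {
    scion <- Biostrings::DNAStringSet(c(SCgene = random_dna(200)))
    root <- Biostrings::DNAStringSet(c(RSgene = random_dna(200)))
    cl <- classifySample(list(id = character(), seq = character(),
                              qual = character()), scion, root)
    expect_equal(cl$accounting$clean_reads, 0)
    expect_true(all(cl$counts == 0))
})
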