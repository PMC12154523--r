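# Small simulation configurations so unit tests run in seconds; the
# full-scale design is exercised in the acceptance suite.
tiny_config <- function(seed = 1, ...) {
    args <- list(nGenes = 30, geneLengthRange = c(200, 400), nMobile = 5,
                 mobilityNear = 0.02, mobilityFar = 0.004,
                 readsPerSample = 2000, readLength = 100,
                 errorRate = 0.005, nReplicates = 3, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simulationConfig, args)
}

# Sensitivity/precision of a recovered mobile set against the planted one.
recovery_stats <- function(found, planted) {
    tp <- length(intersect(found, planted))
    c(sensitivity = tp / length(planted),
      precision = if (length(found)) tp / length(found) else NA_real_)
}
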