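## the repeated-CV comparison runs are shared across test blocks; compute
## them once, lazily, under fixed seeds
.cmpCache <- new.env(parent = emptyenv())

noisyComparison <- function() {
    if (is.null(.cmpCache$noisy)) {
        co <- generateCohort(CohortSpec(labelNoise = 0.15), seed = 101)
        .cmpCache$noisy <- compareMethods(co$features, repeats = 30,
                                          folds = 5, baseSeed = 101)
    }
    .cmpCache$noisy
}

cleanComparison <- function() {
    if (is.null(.cmpCache$clean)) {
        co <- generateCohort(CohortSpec(), seed = 102)
        .cmpCache$clean <- compareMethods(co$features, repeats = 10,
                                          folds = 5, baseSeed = 102)
    }
    .cmpCache$clean
}
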