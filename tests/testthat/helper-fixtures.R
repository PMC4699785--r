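# Shared fixtures: all synthetic, built in code at test time.

# Reduced-scale generator config: 4 species x 12 nests x 3 workers on a
# 500-2300 nm grid at 12 nm (151 variables). Small enough that a full
# identification run takes well under a second.
smallConfig <- function(delta = 1, ...) {
    syntheticConfig(nestsPerSpecies = 12, populationsPerSpecies = 6,
                    gridFrom = 500, gridTo = 2300, gridStep = 12,
                    delta = delta, ...)
}

smallCollection <- function(seed = 42, delta = 1, ...) {
    gen <- generateSpectra(smallConfig(delta = delta, ...), seed = seed)
    truthJoin(gen$spectra, gen$truth)
}

smallSplit <- function(x, seed = 7) {
    makeSplit(x, calibNests = 8, validNests = 4, seed = seed)
}

# Hand-built 2-species toy collection on a 3-point grid.
toyCollection <- function() {
    SpectraSet(
        matrix(c(0.1, 0.2, 0.3,
                 0.4, 0.5, 0.6), nrow = 3),
        c(500, 501, 502),
        data.frame(specimen_id = c("a1", "b1"),
                   nest_id = c("na", "nb"),
                   population_id = c("pa", "pb"),
                   species = c("spA", "spB")))
}

# Prediction records constructor for exclusion-search tests.
makeRecords <- function(values, trueClass, threshold = 1.5,
                        nests = NULL) {
    n <- length(values)
    if (is.null(nests)) nests <- paste0("n", seq_len(n))
    data.frame(specimen_id = paste0("s", seq_len(n)),
               nest_id = nests,
               true_class = as.integer(trueClass),
               value = values,
               assigned_class = ifelse(values <= threshold, 1L, 2L),
               excluded = FALSE,
               stringsAsFactors = FALSE)
}
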