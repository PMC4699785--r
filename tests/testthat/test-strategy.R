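# Independent brute-force oracle for the peel-off (type A) enumeration:
# iterate bitmask subsets and collect "one element vs the rest" splits,
# deduplicated as unordered comparisons.
bruteForceTypeA <- function(c) {
    keys <- character()
    for (mask in seq_len(2^c - 1)) {
        S <- which(bitwAnd(mask, 2^(seq_len(c) - 1)) > 0)
        if (length(S) < 2) next
        for (x in S) {
            g1 <- paste(x, collapse = ",")
            g2 <- paste(sort(setdiff(S, x)), collapse = ",")
            keys <- c(keys, paste(sort(c(g1, g2)), collapse = "|"))
        }
    }
    length(unique(keys))
}

test_that("one-vs-all step counts follow the piecewise rule", {
    expect_equal(stepsOneVsAll(2), 1L)
    expect_equal(stepsOneVsAll(3), 3L)
    expect_equal(stepsOneVsAll(4), 4L)
    expect_equal(stepsOneVsAll(7), 7L)
    expect_error(stepsOneVsAll(1), class = "nirsova_domain_error")
})

test_that("type-A closed form equals brute-force enumeration for c = 2..8", {
    for (c in 2:8) {
        expect_equal(stepsBinaryA(c), bruteForceTypeA(c), info = paste("c =", c))
        expect_equal(length(enumerateModelsBinaryA(c)), stepsBinaryA(c),
                     info = paste("c =", c))
    }
    expect_equal(stepsBinaryA(2), 1L)
    expect_equal(length(enumerateModelsBinaryA(3)), 6L)  # hand enumeration
    expect_equal(stepsBinaryA(4), 22L)
    expect_equal(stepsBinaryA(7), 420L)
})

test_that("balanced-halving (type B) enumeration gives the known counts", {
    expect_equal(stepsBinaryB(2), 1L)
    # c = 4: 3 top-level 2+2 partitions plus the 6 pairwise models
    expect_equal(stepsBinaryB(4), 9L)
    # c = 7: 35 (4+3) + 105 (2+2) + 105 (2+1) + 21 pairs
    expect_equal(stepsBinaryB(7), 266L)
    # deterministic run to run
    expect_identical(stepsBinaryB(5), stepsBinaryB(5))
})

test_that("enumerations return unordered, disjoint, non-empty, unique comparisons", {
    for (enum in list(enumerateModelsBinaryA, enumerateModelsBinaryB)) {
        for (c in c(2, 4, 5)) {
            models <- enum(c)
            keys <- vapply(models, function(m)
                paste(sort(c(paste(sort(m$group1), collapse = ","),
                             paste(sort(m$group2), collapse = ","))),
                      collapse = "|"), "")
            expect_false(anyDuplicated(keys) > 0)
            for (m in models) {
                expect_gt(length(m$group1), 0)
                expect_gt(length(m$group2), 0)
                expect_length(intersect(m$group1, m$group2), 0)
            }
        }
    }
})

test_that("strategy costs are ordered and grow at the expected rates", {
    for (c in 3:8) {
        expect_lte(stepsOneVsAll(c), stepsBinaryB(c))
        expect_lte(stepsBinaryB(c), stepsBinaryA(c))
    }
    # one-vs-all is linear; type A grows like c * 2^c
    ova <- vapply(2:10, stepsOneVsAll, 1L)
    expect_equal(diff(ova[-1]), rep(1L, 7))
    a <- vapply(2:10, stepsBinaryA, 1L)
    ratio <- a[-1] / a[-length(a)]
    expect_true(all(ratio > 2 & ratio < 7))   # supra-exponential doubling
    expect_gt(a[9] / 2^10, 4)                 # Theta(c * 2^c) scale at c = 10
})

test_that("elaboration time is steps times per-model hours, displayed half-up", {
    expect_equal(elaborationHours(4, "one_vs_all")$hoursDisplay, 5.3)
    expect_equal(elaborationHours(4, "binary_A")$hoursDisplay, 29.3)
    expect_equal(elaborationHours(4, "binary_B")$hours, 12)
    expect_equal(elaborationHours(7, "one_vs_all")$hoursDisplay, 9.3)
    expect_equal(elaborationHours(7, "binary_A")$hours, 560)
    expect_equal(elaborationHours(7, "binary_B")$hoursDisplay, 354.7)
    # one model regardless of strategy at c = 2
    for (s in c("one_vs_all", "binary_A", "binary_B"))
        expect_equal(elaborationHours(2, s)$hours, 4 / 3)
    # unit per-model time returns bare model counts
    tab <- strategyCostTable(2:5, perModelHours = 1)
    expect_equal(tab$hours, tab$models)
    expect_error(elaborationHours(4, "one_vs_all", perModelHours = 0),
                 class = "nirsova_domain_error")
})
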