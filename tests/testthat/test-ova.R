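test_that("one-vs-all assigns by threshold with ties to Class 1", {
    x <- smallCollection(seed = 20)
    split <- smallSplit(x)
    task <- runOneVsAll(x, split, "sp2", backendSpec("pls", nFactors = 4))
    rec <- task$records
    expect_setequal(rec$specimen_id,
                    specimenData(splitSubset(x, split, "validation"))$specimen_id)
    expect_equal(rec$assigned_class, ifelse(rec$value <= 1.5, 1L, 2L))
    expect_false(any(rec$excluded))
})

test_that("well-separated synthetic data classify perfectly before exclusion", {
    # no noise at all: species spectra are exactly their expected curves
    x <- smallCollection(seed = 21, nestSd = 0, specimenSd = 0, replicaSd = 0)
    split <- smallSplit(x)
    task <- runOneVsAll(x, split, "sp1", backendSpec("pls", nFactors = 3))
    expect_true(all(task$records$assigned_class == task$records$true_class))
})

test_that("exclusion search reproduces the hand-stepped worked example", {
    rec <- makeRecords(values = c(1.10, 1.30, 1.44, 1.20),
                       trueClass = c(1, 1, 2, 2))
    out <- exclusionSearch(rec, threshold = 1.5, cap = c(1, 2))
    expect_equal(out@status, "success")
    expect_equal(c(out@lo, out@hi), c(1.20, 1.80))
    expect_equal(out@retainedTruePositives, 1L)   # the 1.10 specimen
    expect_equal(out@excludedClass1, 1L)          # the 1.30 specimen
    expect_equal(out@falsePositivesRemaining, 0L)
})

test_that("no false positives means success with an empty interval", {
    rec <- makeRecords(values = c(1.1, 1.2, 1.9, 1.8),
                       trueClass = c(1, 1, 2, 2))
    out <- exclusionSearch(rec, 1.5, cap = c(1, 2))
    expect_equal(out@status, "success")
    expect_equal(out@nSteps, 0L)
    expect_true(is.na(out@lo))
    expect_equal(out@retainedTruePositives, 2L)
    expect_equal(out@excludedClass1, 0L)
})

test_that("a false positive beyond the Class-1 code cap forces failure", {
    # mirrors the failure rows of published Table-2-style reports
    rec <- makeRecords(values = c(1.2, 0.90), trueClass = c(1, 2))
    out <- exclusionSearch(rec, 1.5, cap = c(1, 2))
    expect_equal(out@status, "failure")
    expect_equal(out@falsePositivesRemaining, 1L)
    expect_equal(c(out@lo, out@hi), c(1, 2))      # search stopped at the cap
    # same semantics on the 0/1 code scale
    rec01 <- makeRecords(values = c(0.2, -0.05), trueClass = c(1, 2),
                         threshold = 0.5)
    out01 <- exclusionSearch(rec01, 0.5, cap = c(0, 1))
    expect_equal(out01@status, "failure")
})

test_that("interval bounds stay on the 0.05 lattice and widen monotonically", {
    set.seed(31)
    for (i in 1:25) {
        n <- sample(10:40, 1)
        rec <- makeRecords(values = runif(n, 0.8, 2.2),
                           trueClass = sample(1:2, n, replace = TRUE))
        out <- exclusionSearch(rec, 1.5, cap = c(1, 2))
        if (!is.na(out@lo)) {
            expect_equal(out@lo * 20, round(out@lo * 20))
            expect_equal(out@hi * 20, round(out@hi * 20))
            expect_equal(out@hi - 1.5, 1.5 - out@lo, tolerance = 1e-10)
        }
        # monotonicity: excluded count grows, false positives shrink per step
        isFP <- rec$true_class == 2L & rec$value <= 1.5
        prevEx <- -1L; prevFP <- Inf
        for (k in 0:10) {
            excl <- if (k == 0) rep(FALSE, n) else
                rec$value >= 1.5 - k * 0.05 & rec$value <= 1.5 + k * 0.05
            expect_gte(sum(excl), prevEx)
            expect_lte(sum(isFP & !excl), prevFP)
            prevEx <- sum(excl); prevFP <- sum(isFP & !excl)
        }
    }
})

test_that("nestmate propagation identifies whole nests from one retained member", {
    rec <- makeRecords(values = c(1.1, 1.3, 1.6, 1.9),
                       trueClass = c(1, 1, 1, 2),
                       nests = c("nA", "nA", "nA", "nB"))
    # with the interval [1.25, 1.75]: s1 (1.1) retained, s2 and s3 excluded
    out2 <- methods::new("ExclusionOutcome", status = "success",
                         lo = 1.25, hi = 1.75, nSteps = 5L,
                         retainedTruePositives = 1L, excludedClass1 = 2L,
                         falsePositivesRemaining = 0L)
    ids <- nestmatePropagate(rec, out2)
    expect_setequal(ids, c("s1", "s2", "s3"))   # the whole nest nA
})

test_that("propagation never adds Class-2 specimens and needs a retained member", {
    rec <- makeRecords(values = c(1.4, 1.45, 1.3),
                       trueClass = c(1, 1, 2),
                       nests = c("nA", "nA", "nA"))
    out <- methods::new("ExclusionOutcome", status = "success",
                        lo = 1.3, hi = 1.7, nSteps = 4L,
                        retainedTruePositives = 0L, excludedClass1 = 2L,
                        falsePositivesRemaining = 0L)
    # everything Class-1 is excluded: no retained member, nothing identified
    expect_length(nestmatePropagate(rec, out), 0L)

    # idempotence: applying the rule to its own output changes nothing
    rec2 <- makeRecords(values = c(1.1, 1.4, 1.35),
                        trueClass = c(1, 1, 2),
                        nests = c("nA", "nA", "nB"))
    out2 <- methods::new("ExclusionOutcome", status = "success",
                         lo = 1.3, hi = 1.7, nSteps = 4L,
                         retainedTruePositives = 1L, excludedClass1 = 1L,
                         falsePositivesRemaining = 0L)
    ids <- nestmatePropagate(rec2, out2)
    expect_setequal(ids, c("s1", "s2"))
    expect_false("s3" %in% ids)                 # Class-2 nestmate of nobody

    # failure outcomes cannot be propagated
    fail <- methods::new("ExclusionOutcome", status = "failure",
                         lo = 1, hi = 2, nSteps = 10L,
                         retainedTruePositives = 0L, excludedClass1 = 0L,
                         falsePositivesRemaining = 1L)
    expect_error(nestmatePropagate(rec2, fail),
                 class = "nirsova_state_error")
})

test_that("excluded specimens with no retained nestmate stay unidentified", {
    rec <- makeRecords(values = c(1.1, 1.4), trueClass = c(1, 1),
                       nests = c("nA", "nB"))
    out <- methods::new("ExclusionOutcome", status = "success",
                        lo = 1.35, hi = 1.65, nSteps = 3L,
                        retainedTruePositives = 1L, excludedClass1 = 1L,
                        falsePositivesRemaining = 0L)
    expect_setequal(nestmatePropagate(rec, out), "s1")
})
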