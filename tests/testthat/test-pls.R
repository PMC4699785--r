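test_that("rank-1 noiseless problem is recovered exactly with one factor", {
    set.seed(10)
    t <- rnorm(12)
    p <- rnorm(6)
    X <- tcrossprod(t, p)               # rank-1 predictors
    y <- 2 * t + 1                      # collinear with the latent direction
    fit <- fitPls(X, y, nFactors = 1)
    expect_lt(max(abs(predictValues(fit, X) - y)), 1e-10)
})

test_that("NIPALS equals ordinary least squares at full rank", {
    set.seed(20)
    n <- 15; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fitPls(X, y, nFactors = p)
    ols <- stats::fitted(stats::lm(y ~ X))
    expect_lt(max(abs(predictValues(fit, X) - ols)), 1e-8)
})

test_that("score vectors are orthogonal and training RSS never increases", {
    set.seed(30)
    X <- matrix(rnorm(25 * 40), 25, 40)
    y <- rnorm(25)
    fit <- fitPls(X, y, nFactors = 8)
    G <- crossprod(fit@scores)
    offDiag <- G - diag(diag(G))
    expect_lt(max(abs(offDiag)) / max(diag(G)), 1e-8)

    rss <- vapply(1:8, function(a) {
        f <- fitPls(X, y, nFactors = a)
        sum((y - predictValues(f, X))^2)
    }, 0)
    expect_true(all(diff(rss) <= 1e-10))
})

test_that("predictions are affine-equivariant in the response codes", {
    set.seed(40)
    X <- matrix(rnorm(20 * 30), 20, 30)
    y <- rep(c(1, 2), each = 10)
    f1 <- fitPls(X, y, nFactors = 3)
    f2 <- fitPls(X, y + 1, nFactors = 3)
    Xnew <- matrix(rnorm(5 * 30), 5, 30)
    expect_equal(predictValues(f2, Xnew), predictValues(f1, Xnew) + 1,
                 tolerance = 1e-10)
})

test_that("the calibration mean spectrum predicts the mean response", {
    set.seed(50)
    X <- matrix(rnorm(18 * 25), 18, 25)
    y <- rep(c(1, 2), 9)
    for (a in c(1, 4)) {
        fit <- fitPls(X, y, nFactors = a)
        expect_equal(drop(predictValues(fit, matrix(colMeans(X), 1))),
                     mean(y), tolerance = 1e-10)
    }
})

test_that("degenerate inputs raise domain errors", {
    X <- matrix(rnorm(20), 5, 4)
    expect_error(fitPls(X, rep(1, 5), nFactors = 1),
                 class = "nirsova_domain_error")       # constant target
    expect_error(fitPls(X, c(1, 1, 2, 2, 1), nFactors = 10),
                 class = "nirsova_domain_error")       # beyond rank bound
    fit <- fitPls(X, c(1, 1, 2, 2, 1), nFactors = 2)
    expect_error(predictValues(fit, matrix(0, 1, 7)),
                 class = "nirsova_validation_error")   # grid mismatch
})

test_that("factor selection maximises validation rate, ties to fewer factors", {
    # signal lives in 2 latent dimensions
    set.seed(60)
    n <- 40; p <- 30
    scoresA <- rnorm(n); scoresB <- rnorm(n)
    dirA <- rnorm(p); dirB <- rnorm(p)
    cls <- rep(c(1, 2), each = n / 2)
    X <- outer(scoresA + (cls - 1.5), dirA) + outer(scoresB, dirB) +
        matrix(rnorm(n * p, sd = 0.1), n, p)
    sel <- sample(n, 25)
    Xc <- X[sel, ]; yc <- cls[sel]
    Xv <- X[-sel, ]; yv <- cls[-sel]
    candidates <- 1:8
    pick <- selectPlsFactors(Xc, yc, Xv, yv, candidates)
    # exhaustive scoring oracle
    rates <- vapply(candidates, function(a) {
        f <- fitPls(Xc, yc, nFactors = a)
        mean(ifelse(predictValues(f, Xv) <= 1.5, 1, 2) == yv)
    }, 0)
    best <- candidates[which.max(rates)]
    expect_gte(pick, 2 - 1)               # needs the latent structure
    expect_lte(abs(pick - best), 2)
    expect_equal(rates[match(pick, candidates)], max(rates))

    expect_equal(selectPlsFactors(Xc, yc, Xv, yv, candidates = 5), 5L)
    expect_error(selectPlsFactors(Xc, yc, Xv, yv, candidates = integer()),
                 class = "nirsova_domain_error")
})

test_that("equal-performing candidates resolve to the smallest factor count", {
    # perfectly separated: every factor count classifies everything right
    set.seed(70)
    X <- rbind(matrix(rnorm(10 * 12, mean = 0), 10, 12),
               matrix(rnorm(10 * 12, mean = 5), 10, 12))
    y <- rep(c(1, 2), each = 10)
    expect_equal(selectPlsFactors(X, y, X, y, candidates = 1:6), 1L)
})

test_that("NIPALS matches an independent PLS implementation", {
    suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
    set.seed(80)
    n <- 20; p <- 50
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
    y <- rnorm(n)
    mine <- fitPls(X, y, nFactors = 3)
    ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
    refPred <- predict(ref, X)$predict[, 1, 3]
    expect_lt(max(abs(predictValues(mine, X) - refPred)), 1e-6)
})
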