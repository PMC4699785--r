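#' Fit a NIPALS PLS1 regression
#'
#' Factors are extracted sequentially: the weight vector is the covariance
#' direction between the current predictor residual and the response
#' residual, scores are the projection of the residual onto it, and both
#' residuals are deflated by the factor before the next extraction. Data are
#' column-centred internally (means are stored and re-applied at prediction
#' time); variables are never standardised, following common chemometric
#' practice for reflectance spectra on a shared scale.
#'
#' @param X numeric matrix, specimens in rows and wavelengths in columns.
#' @param y numeric response, one value per specimen — for classification,
#'   the two class codes.
#' @param nFactors number of latent factors, `1 <= nFactors <=
#'   min(nrow(X) - 1, ncol(X))`.
#' @param wavelengths optional grid stored with the fit (defaults to column
#'   index).
#' @return a [PlsFit-class].
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' y <- c(1, 1, 1, 1, 2, 2, 2, 2)
#' fit <- fitPls(X, y, nFactors = 2)
#' predictValues(fit, X)
#' @export
fitPls <- function(X, y, nFactors, wavelengths = NULL) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) .valErr("y must have one value per row of X")
    if (stats::var(y) == 0) .domErr("constant response: degenerate target")
    nFactors <- as.integer(nFactors)
    if (nFactors < 1L || nFactors > min(n - 1L, p))
        .domErr(sprintf("nFactors must be in [1, %d]", min(n - 1L, p)))
    if (is.null(wavelengths)) wavelengths <- seq_len(p)

    xMeans <- colMeans(X)
    yMean <- mean(y)
    Xd <- sweep(X, 2L, xMeans)
    yd <- y - yMean
    W <- P <- matrix(0, p, nFactors)
    Tm <- matrix(0, n, nFactors)
    q <- numeric(nFactors)
    for (a in seq_len(nFactors)) {
        w <- drop(crossprod(Xd, yd))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12)
            .domErr(sprintf("factor extraction collapsed at factor %d; reduce nFactors", a))
        w <- w / nw
        t <- drop(Xd %*% w)
        tt <- sum(t^2)
        if (tt < 1e-24)
            .domErr(sprintf("zero-variance score at factor %d; reduce nFactors", a))
        pv <- drop(crossprod(Xd, t)) / tt
        qa <- sum(yd * t) / tt
        Xd <- Xd - tcrossprod(t, pv)
        yd <- yd - t * qa
        W[, a] <- w; P[, a] <- pv; q[a] <- qa; Tm[, a] <- t
    }
    B <- drop(W %*% solve(crossprod(P, W), q))
    methods::new("PlsFit",
        nFactors = nFactors, wavelengths = as.numeric(wavelengths),
        xMeans = xMeans, yMean = yMean,
        weights = W, loadings = P, qLoadings = q, scores = Tm,
        coefficients = B, intercept = yMean - sum(xMeans * B))
}

#' Continuous prediction values
#'
#' Every specimen receives one continuous prediction value; values are never
#' clipped to the class-code interval — values beyond the codes are
#' meaningful to the exclusion-search failure rule.
#'
#' @param object a [PlsFit-class] or [FittedBackend-class].
#' @param x numeric matrix (specimens x wavelengths) or [SpectraSet-class]
#'   on the training grid.
#' @return numeric vector of prediction values, one per specimen.
#' @rdname predictValues
#' @export
setMethod("predictValues", "PlsFit", function(object, x) {
    x <- .predMatrix(x, object@wavelengths)
    drop(x %*% object@coefficients) + object@intercept
})

.predMatrix <- function(x, grid) {
    if (methods::is(x, "SpectraSet")) {
        if (!identical(as.numeric(wavelengths(x)), as.numeric(grid)))
            .valErr("collection grid does not match the training grid")
        return(.specMatrix(x))
    }
    x <- as.matrix(x)
    if (ncol(x) != length(grid))
        .valErr("prediction matrix does not match the training grid")
    x
}

#' Choose the PLS factor count by validation classification rate
#'
#' Reproducible surrogate for the manual inspection step of classical
#' chemometrics software: every candidate factor count is scored by the
#' correct-classification rate of a held-out selection set at the code
#' midpoint threshold, and the smallest candidate achieving the maximum is
#' returned.
#'
#' @param X,y calibration matrix (specimens x wavelengths) and class codes.
#' @param Xval,yval selection-set matrix and true class codes.
#' @param candidates candidate factor counts (default 1..20, capped at the
#'   calibration rank bound).
#' @param classCodes the two class codes (default `c(1, 2)`).
#' @return the selected factor count (integer).
#' @export
selectPlsFactors <- function(X, y, Xval, yval, candidates = 1:20,
                             classCodes = c(1, 2)) {
    if (!length(candidates)) .domErr("candidate list is empty")
    X <- as.matrix(X); Xval <- as.matrix(Xval)
    cap <- min(nrow(X) - 1L, ncol(X))
    candidates <- sort(unique(as.integer(candidates)))
    candidates <- candidates[candidates >= 1L & candidates <= cap]
    if (!length(candidates)) .domErr("no candidate within the rank bound")
    threshold <- mean(classCodes)
    # one NIPALS pass at the largest candidate; coefficients per count fall
    # out of the accumulated weights/loadings
    full <- fitPls(X, y, max(candidates))
    rates <- vapply(candidates, function(a) {
        B <- drop(full@weights[, seq_len(a), drop = FALSE] %*%
            solve(crossprod(full@loadings[, seq_len(a), drop = FALSE],
                            full@weights[, seq_len(a), drop = FALSE]),
                  full@qLoadings[seq_len(a)]))
        pred <- drop(sweep(Xval, 2L, full@xMeans) %*% B) + full@yMean
        assigned <- ifelse(pred <= threshold, classCodes[1L], classCodes[2L])
        mean(assigned == yval)
    }, numeric(1L))
    candidates[which.max(rates)]  # which.max takes the first (smallest) tie
}
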