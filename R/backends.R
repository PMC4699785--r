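#' Build a backend specification
#'
#' Class codes follow the backend family: PLS regresses on codes `(1, 2)`
#' with decision threshold 1.5; random-forest and neural-network backends
#' use `(0, 1)` with threshold 0.5. A specimen with prediction value at or
#' below the threshold is assigned to Class 1.
#'
#' @param kind `"pls"`, `"rf"` or `"ann"`.
#' @param ... hyperparameters: `nFactors` (pls), `ntree` (rf, default
#'   1000), `mtry` (rf, default the regression default `floor(p/3)`),
#'   `nHidden` (ann, default chosen from the calibration size).
#' @param classCodes override the family default codes.
#' @return a [BackendSpec-class].
#' @examples
#' backendSpec("pls", nFactors = 10)
#' backendSpec("rf")
#' @export
backendSpec <- function(kind = c("pls", "rf", "ann"), ..., classCodes = NULL) {
    kind <- match.arg(kind)
    if (is.null(classCodes))
        classCodes <- if (kind == "pls") c(1, 2) else c(0, 1)
    hp <- list(...)
    known <- switch(kind, pls = "nFactors", rf = c("ntree", "mtry"),
                    ann = c("nHidden", "maxit", "decay"))
    bad <- setdiff(names(hp), known)
    if (length(bad))
        .domErr(paste0("unknown hyperparameter(s) for ", kind, ": ",
                       paste(bad, collapse = ", ")))
    if (kind == "rf" && is.null(hp$ntree)) hp$ntree <- 1000L
    tryCatch(methods::new("BackendSpec", kind = kind, hyperparameters = hp,
                          classCodes = as.numeric(classCodes),
                          threshold = mean(classCodes)),
             error = function(e) .domErr(conditionMessage(e)))
}

setMethod("show", "BackendSpec", function(object) {
    hp <- object@hyperparameters
    cat("BackendSpec<", object@kind, "> codes (",
        paste(object@classCodes, collapse = ", "), ") threshold ",
        object@threshold, "\n", sep = "")
    if (length(hp))
        cat("  ", paste(names(hp), unlist(hp), sep = " = ", collapse = ", "),
            "\n", sep = "")
})

#' Fit a prediction backend
#'
#' Dispatches on the spec kind: `"pls"` routes to [fitPls()]; `"rf"` fits a
#' regression random forest on the numeric class codes (`ntree` 1000 by
#' default); `"ann"` fits a single-hidden-layer feed-forward network trained
#' by backpropagation on 0/1 codes with a sigmoid output. Continuous
#' prediction values come back from all three through [predictValues()].
#'
#' @param spec a [BackendSpec-class].
#' @param X calibration matrix, specimens in rows (already centred for pls;
#'   rf/ann are scale-invariant enough that the same centred matrix is
#'   used).
#' @param y numeric class codes matching `spec@classCodes`.
#' @param wavelengths grid stored with the fit.
#' @param centering optional [CenteringModel-class] recorded for later
#'   application to new data.
#' @param seed integer seed honoured by the stochastic backends; the same
#'   seed yields identical fits.
#' @return a [FittedBackend-class].
#' @export
fitBackend <- function(spec, X, y, wavelengths = NULL, centering = NULL,
                       seed = NULL) {
    stopifnot(methods::is(spec, "BackendSpec"))
    X <- as.matrix(X)
    if (!all(y %in% spec@classCodes))
        .valErr("y contains values other than the spec class codes")
    if (length(unique(y)) != 2L)
        .domErr("both class codes must be present in y")
    if (is.null(wavelengths)) wavelengths <- seq_len(ncol(X))
    if (is.null(centering))
        centering <- methods::new("CenteringModel",
            wavelengths = as.numeric(wavelengths),
            means = rep(0, ncol(X)))
    hp <- spec@hyperparameters
    if (!is.null(seed)) set.seed(as.integer(seed))
    fit <- switch(spec@kind,
        pls = {
            if (is.null(hp$nFactors))
                .domErr("pls backend needs hyperparameter nFactors (or use runOneVsAll, which selects it)")
            fitPls(X, y, hp$nFactors, wavelengths)
        },
        rf = {
            args <- list(x = X, y = as.numeric(y), ntree = hp$ntree)
            if (!is.null(hp$mtry)) args$mtry <- hp$mtry
            # regression on the two numeric class codes is deliberate: it is
            # what yields the continuous prediction values the exclusion
            # search needs, so silence the two-level-response warning
            suppressWarnings(do.call(randomForest::randomForest, args))
        },
        ann = {
            nh <- hp$nHidden
            if (is.null(nh)) nh <- max(2L, min(8L, floor(nrow(X) / 12)))
            y01 <- (y - spec@classCodes[1L]) /
                   (spec@classCodes[2L] - spec@classCodes[1L])
            nnet::nnet(X, y01, size = nh, linout = FALSE, trace = FALSE,
                       maxit = if (is.null(hp$maxit)) 300L else hp$maxit,
                       decay = if (is.null(hp$decay)) 1e-3 else hp$decay,
                       MaxNWts = (ncol(X) + 2L) * nh + nh + 1L + 1000L)
        })
    methods::new("FittedBackend", spec = spec, fit = fit,
                 centering = centering, wavelengths = as.numeric(wavelengths))
}

#' @rdname predictValues
#' @export
setMethod("predictValues", "FittedBackend", function(object, x) {
    x <- .predMatrix(x, object@wavelengths)
    spec <- object@spec
    switch(spec@kind,
        pls = predictValues(object@fit, x),
        rf = as.numeric(stats::predict(object@fit, x)),
        ann = {
            p01 <- as.numeric(stats::predict(object@fit, x))
            spec@classCodes[1L] + p01 * (spec@classCodes[2L] - spec@classCodes[1L])
        })
})

#' Assign classes from prediction values
#'
#' A value at or below the threshold assigns Class 1 (the threshold itself
#' included), otherwise Class 2.
#'
#' @param values continuous prediction values.
#' @param threshold decision threshold (code midpoint).
#' @return integer vector of 1s and 2s.
#' @export
assignClasses <- function(values, threshold) {
    ifelse(values <= threshold, 1L, 2L)
}
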