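#' Trim a collection to a wavelength window
#'
#' Sensor and lighting limitations make the extremes of a VIS/NIR grid
#' noisy; the standard window keeps the closed interval \[500, 2300\] nm.
#' On a 350-2,500 nm grid at 1 nm this retains exactly 1,801 variables.
#'
#' @param x a [SpectraSet-class].
#' @param trimLow,trimHigh window bounds in nm (closed interval).
#' @return the trimmed [SpectraSet-class].
#' @export
trimWavelengths <- function(x, trimLow = 500, trimHigh = 2300) {
    if (trimLow >= trimHigh) .domErr("trimLow must be < trimHigh")
    keep <- wavelengths(x) >= trimLow & wavelengths(x) <= trimHigh
    if (!any(keep)) .valErr("no wavelengths remain after trimming")
    x[keep, ]
}

#' Deterministic sparse wavelength subsample
#'
#' Retains exactly the wavelengths `start, start+step, ...,
#' start+(n-1)*step`. With the defaults (500 nm start, 12 nm step, 150
#' variables) the last retained wavelength is 2,288 nm; this is the reduced
#' variable set used by backends that cannot handle the full grid.
#'
#' @param x a [SpectraSet-class].
#' @param start first wavelength (nm).
#' @param step increment (nm).
#' @param n number of wavelengths.
#' @return the subsampled [SpectraSet-class].
#' @export
subsampleGrid <- function(x, start = 500, step = 12, n = 150) {
    if (n < 1L || step <= 0) .domErr("need n >= 1 and step > 0")
    want <- start + step * (seq_len(n) - 1L)
    idx <- match(want, wavelengths(x))
    if (anyNA(idx))
        .valErr(paste0("requested wavelengths not on the grid: ",
                       paste(utils::head(want[is.na(idx)], 5L), collapse = ", ")))
    x[idx, ]
}

#' Fit a per-wavelength centring model on a calibration set
#'
#' Means are computed on the calibration collection only; applying the model
#' to validation data subtracts the calibration means, which keeps the
#' validation set independent of the preprocessing.
#'
#' @param calibration a non-empty [SpectraSet-class].
#' @return a [CenteringModel-class].
#' @export
fitCentering <- function(calibration) {
    if (ncol(calibration) == 0L) .valErr("calibration set is empty")
    methods::new("CenteringModel",
        wavelengths = wavelengths(calibration),
        means = rowMeans(reflectance(calibration)))
}

#' Apply a centring model
#' @param model a [CenteringModel-class].
#' @param x a [SpectraSet-class] or numeric matrix (specimens x wavelengths).
#' @return the centred object, same class as `x`.
#' @rdname applyCentering
#' @export
setMethod("applyCentering", signature("CenteringModel", "SpectraSet"),
    function(model, x) {
        if (!identical(model@wavelengths, wavelengths(x)))
            .valErr("centring model grid does not match the collection grid")
        SummarizedExperiment::assay(x, "reflectance") <-
            reflectance(x) - model@means
        x
    })

#' @rdname applyCentering
#' @export
setMethod("applyCentering", signature("CenteringModel", "matrix"),
    function(model, x) {
        if (ncol(x) != length(model@means))
            .valErr("matrix has wrong number of wavelength columns")
        sweep(x, 2L, model@means)
    })

# Internal: specimens-in-rows matrix view used by the model layer.
.specMatrix <- function(x) t(reflectance(x))
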