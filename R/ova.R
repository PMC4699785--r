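# One-vs-all identification: fit on the calibration side only, give every
# validation specimen a continuous prediction value, then push false
# positives out with a symmetric exclusion interval and recover excluded
# Class-1 specimens through their nestmates.

#' Run one one-vs-all prediction task
#'
#' The named species is Class 1; all remaining species are pooled into
#' Class 2. Centring is fitted on the calibration side and applied with
#' those means to both sides; the backend is fitted on calibration spectra
#' only. When the backend is PLS and `nFactors` is not given, the factor
#' count is selected by validation classification rate (smallest count at
#' the maximum).
#'
#' @param x labelled [SpectraSet-class].
#' @param split a [NestSplit-class] covering the collection.
#' @param class1 species treated as Class 1.
#' @param spec a [BackendSpec-class].
#' @param seed seed for stochastic backends and factor selection.
#' @return list with `records` (data.frame: `specimen_id`, `nest_id`,
#'   `true_class`, `value`, `assigned_class`, `excluded`), `backend` (the
#'   [FittedBackend-class]), `settings` (resolved hyperparameters) and
#'   `spec`.
#' @export
runOneVsAll <- function(x, split, class1, spec = backendSpec("pls"),
                        seed = 1) {
    cd <- specimenData(x)
    if (!class1 %in% cd$species) .valErr(paste("unknown species:", class1))
    cal <- splitSubset(x, split, "calibration")
    val <- splitSubset(x, split, "validation")
    if (ncol(val) == 0L) .valErr("validation set is empty")
    if (ncol(cal) == 0L) .valErr("calibration set is empty")

    centering <- fitCentering(cal)
    Xcal <- applyCentering(centering, .specMatrix(cal))
    Xval <- applyCentering(centering, .specMatrix(val))
    codes <- spec@classCodes
    yCal <- ifelse(specimenData(cal)$species == class1, codes[1L], codes[2L])
    yVal <- ifelse(specimenData(val)$species == class1, codes[1L], codes[2L])
    if (length(unique(yCal)) != 2L)
        .valErr("calibration set must contain Class 1 and Class 2 specimens")

    settings <- spec@hyperparameters
    if (spec@kind == "pls" && is.null(settings$nFactors)) {
        settings$nFactors <- selectPlsFactors(Xcal, yCal, Xval, yVal,
                                              classCodes = codes)
        spec <- backendSpec("pls", nFactors = settings$nFactors,
                            classCodes = codes)
    }
    fitted <- fitBackend(spec, Xcal, yCal, wavelengths = wavelengths(x),
                         centering = centering, seed = seed)
    values <- predictValues(fitted, Xval)
    vd <- specimenData(val)
    records <- data.frame(
        specimen_id = vd$specimen_id,
        nest_id = vd$nest_id,
        true_class = ifelse(vd$species == class1, 1L, 2L),
        value = values,
        assigned_class = assignClasses(values, spec@threshold),
        excluded = FALSE,
        stringsAsFactors = FALSE, row.names = NULL)
    list(records = records, backend = fitted, settings = settings, spec = spec)
}

.onLattice <- function(x) round(x * 20) / 20   # snap to the 0.05 lattice

#' Exclusion-interval search to zero false positives
#'
#' Starting from the empty interval at the class-code midpoint, a closed
#' symmetric interval is widened by 0.05 on each side per step (so the
#' first step spans threshold +/- 0.05, i.e. 1.45-1.55 for PLS codes) and
#' specimens whose prediction value falls inside are excluded from
#' identification. The search stops at the first interval leaving zero
#' false positives — Class-2 specimens assigned to Class 1 and not excluded
#' — which makes every retained Class-1 assignment unambiguous. If the
#' interval reaches the cap (the closed interval between the class codes)
#' with false positives remaining — their values lie beyond the Class-1
#' code — the task fails: no interval can rescue it.
#'
#' @param records prediction records as returned by [runOneVsAll()].
#' @param threshold class-code midpoint.
#' @param halfStep per-side widening increment (default 0.05).
#' @param cap numeric(2): the class codes bounding the search.
#' @return an [ExclusionOutcome-class]. Failure is a status, not an error.
#' @examples
#' rec <- data.frame(specimen_id = c("a", "b", "c", "d"),
#'     nest_id = c("n1", "n1", "n2", "n2"),
#'     true_class = c(1L, 1L, 2L, 2L),
#'     value = c(1.10, 1.30, 1.44, 1.20),
#'     assigned_class = c(1L, 1L, 1L, 1L), excluded = FALSE)
#' exclusionSearch(rec, 1.5, cap = c(1, 2))
#' @export
exclusionSearch <- function(records, threshold, halfStep = 0.05,
                            cap = c(1, 2)) {
    if (!nrow(records)) .valErr("no prediction records")
    if (length(cap) != 2L || cap[1L] >= cap[2L])
        .domErr("cap must be the two class codes, increasing")
    maxSteps <- ceiling((threshold - cap[1L]) / halfStep)
    isTP <- records$true_class == 1L & records$assigned_class == 1L
    isFP <- records$true_class == 2L & records$assigned_class == 1L
    for (k in 0:maxSteps) {
        if (k == 0L) {
            excl <- rep(FALSE, nrow(records))
            lo <- hi <- NA_real_
        } else {
            lo <- max(.onLattice(threshold - k * halfStep), cap[1L])
            hi <- min(.onLattice(threshold + k * halfStep), cap[2L])
            excl <- records$value >= lo & records$value <= hi
        }
        fpLeft <- sum(isFP & !excl)
        if (fpLeft == 0L || k == maxSteps) {
            return(methods::new("ExclusionOutcome",
                status = if (fpLeft == 0L) "success" else "failure",
                lo = lo, hi = hi, nSteps = as.integer(k),
                retainedTruePositives = as.integer(sum(isTP & !excl)),
                excludedClass1 = as.integer(sum(records$true_class == 1L & excl)),
                falsePositivesRemaining = as.integer(fpLeft)))
        }
    }
}

#' Mark excluded records for a given outcome
#'
#' @param records prediction records.
#' @param outcome an [ExclusionOutcome-class].
#' @return `records` with the `excluded` flag set from the outcome interval.
#' @export
applyExclusion <- function(records, outcome) {
    records$excluded <- if (is.na(outcome@lo)) rep(FALSE, nrow(records))
        else records$value >= outcome@lo & records$value <= outcome@hi
    records
}

#' Nestmate propagation of identifications
#'
#' Excluded Class-1 specimens are treated as identified when at least one
#' nestmate is among the retained (unambiguously identified) Class-1
#' specimens — nests are assumed monospecific. Class-2 specimens are never
#' added; the operation is idempotent.
#'
#' @param records prediction records.
#' @param outcome a successful [ExclusionOutcome-class].
#' @return character vector of identified specimen ids (retained true
#'   positives plus propagated nestmates).
#' @export
nestmatePropagate <- function(records, outcome) {
    if (outcome@status != "success")
        .stateErr("nestmate propagation requires a successful exclusion outcome")
    records <- applyExclusion(records, outcome)
    retained <- records$true_class == 1L & records$assigned_class == 1L &
                !records$excluded
    goodNests <- unique(records$nest_id[retained])
    propagated <- records$true_class == 1L & records$excluded &
                  records$nest_id %in% goodNests
    records$specimen_id[retained | propagated]
}

setMethod("show", "ExclusionOutcome", function(object) {
    cat("ExclusionOutcome:", object@status)
    if (!is.na(object@lo))
        cat(sprintf(" [%.2f, %.2f] (%d steps)", object@lo, object@hi,
                    object@nSteps))
    cat("\n  retained TP:", object@retainedTruePositives,
        " excluded Class 1:", object@excludedClass1,
        " FP remaining:", object@falsePositivesRemaining, "\n")
})
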