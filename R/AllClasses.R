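#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData colData<-
NULL

#' Single-specimen near-infrared spectrum
#'
#' One specimen's reflectance on a wavelength grid together with its
#' specimen/nest/population/species metadata. The species label may be `NA`
#' for material that has not been identified yet.
#'
#' @slot specimenId character(1) unique specimen identifier.
#' @slot nestId character(1) nest (colony) the specimen was sampled from.
#' @slot populationId character(1) population (site) the nest belongs to.
#' @slot species character(1) species label, or `NA` when unknown.
#' @slot wavelengths strictly increasing numeric grid in nm.
#' @slot reflectance finite numeric reflectance, one value per wavelength.
#'
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        specimenId = "character",
        nestId = "character",
        populationId = "character",
        species = "character",
        wavelengths = "numeric",
        reflectance = "numeric"
    )
)

setValidity("Spectrum", function(object) {
    msg <- character()
    if (length(object@specimenId) != 1L) msg <- c(msg, "specimenId must be length 1")
    if (length(object@wavelengths) != length(object@reflectance))
        msg <- c(msg, "wavelengths and reflectance lengths differ")
    if (length(object@wavelengths) && any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    if (any(!is.finite(object@reflectance)))
        msg <- c(msg, "reflectance values must be finite")
    if (length(msg)) msg else TRUE
})

#' Collection of spectra on a shared wavelength grid
#'
#' A [SummarizedExperiment::SummarizedExperiment] specialisation holding a
#' `reflectance` assay with wavelengths in rows and specimens in columns.
#' `rowData` carries the numeric `wavelength` grid (nm); `colData` carries
#' `specimen_id`, `nest_id`, `population_id` and `species` (`NA` allowed).
#'
#' Validity enforces the structural assumptions the identification routine
#' relies on: a strictly increasing shared grid, finite reflectance, unique
#' specimen identifiers, and a hierarchy in which every nest belongs to
#' exactly one population and (when labelled) one species.
#'
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    msg <- character()
    if (!"reflectance" %in% names(assays(object)))
        return("assay 'reflectance' is required")
    if (!"wavelength" %in% colnames(rowData(object)))
        return("rowData column 'wavelength' is required")
    w <- rowData(object)$wavelength
    if (!is.numeric(w) || (length(w) > 1L && any(diff(w) <= 0)))
        msg <- c(msg, "wavelength grid must be numeric and strictly increasing")
    if (any(!is.finite(assay(object, "reflectance"))))
        msg <- c(msg, "reflectance values must be finite")
    cd <- colData(object)
    need <- c("specimen_id", "nest_id", "population_id", "species")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(cd$specimen_id))
        msg <- c(msg, "specimen_id values must be unique")
    if (nrow(cd)) {
        byNest <- split(as.character(cd$population_id), as.character(cd$nest_id))
        bad <- names(byNest)[vapply(byNest, function(x) length(unique(x)), 1L) > 1L]
        if (length(bad))
            msg <- c(msg, paste0("nest(s) mapped to multiple populations: ",
                                 paste(bad, collapse = ", ")))
        sp <- split(as.character(cd$species), as.character(cd$nest_id))
        bad <- names(sp)[vapply(sp, function(x) length(unique(x[!is.na(x)])), 1L) > 1L]
        if (length(bad))
            msg <- c(msg, paste0("nest(s) mapped to multiple species: ",
                                 paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Per-wavelength centring model
#'
#' Column (per-wavelength) means estimated on a calibration set, to be
#' subtracted from any collection sharing the same grid. Centring validation
#' data with calibration means keeps the validation set independent.
#'
#' @slot wavelengths numeric grid the means were computed on.
#' @slot means numeric per-wavelength calibration means.
#' @exportClass CenteringModel
setClass("CenteringModel",
    representation(wavelengths = "numeric", means = "numeric"))

setValidity("CenteringModel", function(object) {
    if (length(object@wavelengths) != length(object@means))
        "wavelengths and means lengths differ" else TRUE
})

#' NIPALS partial least squares fit (PLS1)
#'
#' Latent factors extracted sequentially by NIPALS from column-centred
#' predictors against a single continuous response (here: a two-class code).
#' The regression vector collapses the factors into one coefficient per
#' wavelength plus an intercept, so prediction is a single inner product.
#'
#' @slot nFactors number of latent factors retained.
#' @slot wavelengths training wavelength grid.
#' @slot xMeans,yMean training column means / response mean.
#' @slot weights,loadings p x A factor weight and loading matrices.
#' @slot qLoadings length-A response loadings.
#' @slot scores n x A training score matrix (mutually orthogonal columns).
#' @slot coefficients regression vector, one coefficient per wavelength.
#' @slot intercept scalar intercept on the original (uncentred) scale.
#' @exportClass PlsFit
setClass("PlsFit",
    representation(
        nFactors = "integer",
        wavelengths = "numeric",
        xMeans = "numeric",
        yMean = "numeric",
        weights = "matrix",
        loadings = "matrix",
        qLoadings = "numeric",
        scores = "matrix",
        coefficients = "numeric",
        intercept = "numeric"
    )
)

setValidity("PlsFit", function(object) {
    msg <- character()
    A <- object@nFactors
    if (A < 1L) msg <- c(msg, "nFactors must be >= 1")
    if (ncol(object@weights) != A || ncol(object@scores) != A)
        msg <- c(msg, "factor matrices inconsistent with nFactors")
    if (length(object@coefficients) != length(object@wavelengths))
        msg <- c(msg, "one coefficient per wavelength required")
    if (length(msg)) msg else TRUE
})

#' Prediction-backend specification
#'
#' Uniform contract for the two-class prediction backends. Class codes and
#' the decision threshold (their midpoint) are fixed per backend family:
#' `(1, 2)` with threshold 1.5 for PLS, `(0, 1)` with threshold 0.5 for the
#' random-forest and neural-network backends. The exclusion logic downstream
#' only sees codes and threshold, so it is backend-agnostic.
#'
#' @slot kind one of `"pls"`, `"rf"`, `"ann"`.
#' @slot hyperparameters named list (`nFactors` for pls; `ntree`, `mtry` for
#'   rf; `nHidden` for ann).
#' @slot classCodes numeric(2), Class-1 and Class-2 codes.
#' @slot threshold numeric(1), midpoint of the codes.
#' @exportClass BackendSpec
setClass("BackendSpec",
    representation(
        kind = "character",
        hyperparameters = "list",
        classCodes = "numeric",
        threshold = "numeric"
    )
)

setValidity("BackendSpec", function(object) {
    msg <- character()
    if (!object@kind %in% c("pls", "rf", "ann"))
        msg <- c(msg, "kind must be one of 'pls', 'rf', 'ann'")
    if (length(object@classCodes) != 2L || object@classCodes[1] >= object@classCodes[2])
        msg <- c(msg, "classCodes must be two increasing values")
    if (!isTRUE(all.equal(object@threshold, mean(object@classCodes))))
        msg <- c(msg, "threshold must be the midpoint of classCodes")
    if (length(msg)) msg else TRUE
})

#' Fitted backend wrapper
#'
#' Couples a fitted predictor with the centring model and grid it was
#' trained against, so that prediction on new spectra always applies the
#' calibration-set centring.
#'
#' @slot spec the [BackendSpec-class] that produced the fit.
#' @slot fit the underlying fitted object ([PlsFit-class],
#'   `randomForest`, or `nnet`).
#' @slot centering [CenteringModel-class] fitted on the calibration set.
#' @slot wavelengths training grid.
#' @exportClass FittedBackend
setClass("FittedBackend",
    representation(
        spec = "BackendSpec",
        fit = "ANY",
        centering = "CenteringModel",
        wavelengths = "numeric"
    )
)

#' Population-atomic nest split
#'
#' Assignment of every nest to the calibration or the validation set such
#' that all nests of a population share the assignment and per-species nest
#' counts are honoured.
#'
#' @slot assignment named character, `"calibration"`/`"validation"` per nest.
#' @slot calibNests,validNests named integer targets per species.
#' @slot seed integer seed the assignment was drawn with.
#' @exportClass NestSplit
setClass("NestSplit",
    representation(
        assignment = "character",
        calibNests = "integer",
        validNests = "integer",
        seed = "integer"
    )
)

setValidity("NestSplit", function(object) {
    if (!all(object@assignment %in% c("calibration", "validation")))
        return("assignment values must be 'calibration' or 'validation'")
    if (is.null(names(object@assignment)))
        return("assignment must be named by nest_id")
    TRUE
})

#' Outcome of the zero-false-positive exclusion search
#'
#' @slot status `"success"` (no false positives remain) or `"failure"` (the
#'   interval reached the class-code cap with false positives remaining).
#' @slot lo,hi closed exclusion interval bounds on the 0.05 lattice around
#'   the threshold; `NA` when no widening step was needed.
#' @slot nSteps number of 0.1-wide widening steps taken.
#' @slot retainedTruePositives Class-1 specimens still identified.
#' @slot excludedClass1 Class-1 specimens lost to the interval.
#' @slot falsePositivesRemaining Class-2 specimens still inside Class 1
#'   (always 0 on success).
#' @exportClass ExclusionOutcome
setClass("ExclusionOutcome",
    representation(
        status = "character",
        lo = "numeric",
        hi = "numeric",
        nSteps = "integer",
        retainedTruePositives = "integer",
        excludedClass1 = "integer",
        falsePositivesRemaining = "integer"
    )
)

setValidity("ExclusionOutcome", function(object) {
    msg <- character()
    if (!object@status %in% c("success", "failure"))
        msg <- c(msg, "status must be 'success' or 'failure'")
    if (object@status == "success" && object@falsePositivesRemaining != 0L)
        msg <- c(msg, "success requires zero remaining false positives")
    if (length(msg)) msg else TRUE
})

#' One completed one-vs-all identification task
#'
#' @slot class1 the species treated as Class 1.
#' @slot class2 the pooled remaining species.
#' @slot spec backend specification used.
#' @slot settings resolved hyperparameters (e.g. selected PLS factor count).
#' @slot records per-specimen prediction records (data.frame with
#'   `specimen_id`, `nest_id`, `true_class`, `value`, `assigned_class`,
#'   `excluded`).
#' @slot outcome [ExclusionOutcome-class] of the exclusion search.
#' @slot identified specimen ids identified after nestmate propagation.
#' @exportClass OvaRun
setClass("OvaRun",
    representation(
        class1 = "character",
        class2 = "character",
        spec = "BackendSpec",
        settings = "list",
        records = "data.frame",
        outcome = "ExclusionOutcome",
        identified = "character"
    )
)

#' Identification report over all one-vs-all tasks
#'
#' Table-style summary (one row per Class-1 species plus a totals row) of
#' individuals correct/incorrect before and after exclusion, the exclusion
#' range (or a failure marker), individuals identified after nestmate
#' propagation, and nests identified — with percentages against
#' validation-set denominators.
#'
#' @slot table the summary data.frame.
#' @slot runs list of [OvaRun-class], one per species.
#' @slot conflicts data.frame of specimens identified by more than one task.
#' @slot unclassified validation specimen ids identified by no task.
#' @exportClass IdentificationReport
setClass("IdentificationReport",
    representation(
        table = "data.frame",
        runs = "list",
        conflicts = "data.frame",
        unclassified = "character"
    )
)

#' Hierarchical synthetic-spectrum generator configuration
#'
#' Parameterises collections that mimic the structure of a multi-species
#' nest-based NIR survey: species-specific Gaussian absorption bands on a
#' shared smooth baseline, additive Gaussian nest and specimen effects, and
#' per-wavelength replica noise averaged over repeated scans.
#'
#' @slot nSpecies,populationsPerSpecies,nestsPerSpecies,workersPerNest,replicasPerSpecimen
#'   integer design counts.
#' @slot gridFrom,gridTo,gridStep wavelength grid in nm.
#' @slot speciesBands list (one element per species) of data.frames with
#'   columns `centre`, `width`, `depth` (nm, nm, reflectance units).
#' @slot delta scalar multiplying all species-specific band depths; 0 erases
#'   the species signal entirely.
#' @slot nestSd,specimenSd additive-offset standard deviations.
#' @slot replicaSd per-wavelength noise sd of a single scan (averaging over
#'   replicas divides it by sqrt(replicasPerSpecimen)).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        nSpecies = "integer",
        populationsPerSpecies = "integer",
        nestsPerSpecies = "integer",
        workersPerNest = "integer",
        replicasPerSpecimen = "integer",
        gridFrom = "numeric",
        gridTo = "numeric",
        gridStep = "numeric",
        speciesBands = "list",
        delta = "numeric",
        nestSd = "numeric",
        specimenSd = "numeric",
        replicaSd = "numeric"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    counts <- c(object@nSpecies, object@populationsPerSpecies,
                object@nestsPerSpecies, object@workersPerNest,
                object@replicasPerSpecimen)
    if (any(counts < 1L)) msg <- c(msg, "all design counts must be >= 1")
    if (object@delta < 0) msg <- c(msg, "delta must be >= 0")
    if (any(c(object@nestSd, object@specimenSd, object@replicaSd) < 0))
        msg <- c(msg, "noise scales must be >= 0")
    if (object@gridFrom >= object@gridTo || object@gridStep <= 0)
        msg <- c(msg, "grid must satisfy gridFrom < gridTo, gridStep > 0")
    if (length(object@speciesBands) != object@nSpecies)
        msg <- c(msg, "speciesBands must have one element per species")
    grid <- seq(object@gridFrom, object@gridTo, by = object@gridStep)
    for (b in object@speciesBands) {
        if (!all(c("centre", "width", "depth") %in% colnames(b)))
            msg <- c(msg, "each band table needs centre, width, depth")
        else if (!all(b$centre %in% grid))
            msg <- c(msg, "band centres must lie on the wavelength grid")
    }
    if (length(msg)) msg else TRUE
})
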