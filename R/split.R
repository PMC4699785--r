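#' Population-atomic calibration/validation split at the nest level
#'
#' For each species, nests are split into a calibration and a validation set
#' with all nests of a population assigned together, so the validation set
#' is independent of the calibration material. Targets default to 30
#' calibration and 15 validation nests per species and may be overridden per
#' species (named vectors) when a species has fewer nests. The calibration
#' and validation targets must add up to the species' nest count.
#'
#' A randomised backtracking subset-sum over the species' populations finds
#' an assignment whose validation nests total exactly the target; structures
#' in which no subset of populations can hit the target raise an
#' infeasibility error naming the species.
#'
#' @param x a labelled [SpectraSet-class] (species known for every nest).
#' @param calibNests,validNests scalar or per-species named targets.
#' @param seed integer; the same seed reproduces the assignment.
#' @return a resolved [NestSplit-class].
#' @export
makeSplit <- function(x, calibNests = 30, validNests = 15, seed = 1) {
    cd <- specimenData(x)
    if (anyNA(cd$species))
        .valErr("species labels must be known for every nest before splitting")
    nests <- unique(cd[, c("nest_id", "population_id", "species")])
    speciesList <- sort(unique(nests$species))
    getTarget <- function(tab, sp, what) {
        v <- if (!is.null(names(tab)) && sp %in% names(tab)) tab[[sp]]
             else if (is.null(names(tab))) tab[[1L]]
             else .domErr(paste0("no ", what, " target for species ", sp))
        as.integer(v)
    }
    set.seed(as.integer(seed))
    assignment <- character(); ctab <- vtab <- integer()
    for (sp in speciesList) {
        sub <- nests[nests$species == sp, ]
        ct <- getTarget(calibNests, sp, "calibration")
        vt <- getTarget(validNests, sp, "validation")
        if (ct + vt != nrow(sub))
            .infeasErr(sprintf(
                "species %s has %d nests but %d calibration + %d validation requested",
                sp, nrow(sub), ct, vt))
        popSizes <- table(sub$population_id)
        pops <- sample(names(popSizes))       # random order -> random solution
        sizes <- as.integer(popSizes[pops])
        pick <- .subsetSum(sizes, vt)
        if (is.null(pick))
            .infeasErr(sprintf(
                "species %s: population structure cannot yield %d validation nests (population sizes %s)",
                sp, vt, paste(sort(as.integer(popSizes)), collapse = "+")))
        validPops <- pops[pick]
        a <- ifelse(sub$population_id %in% validPops, "validation", "calibration")
        names(a) <- sub$nest_id
        assignment <- c(assignment, a)
        ctab[sp] <- ct; vtab[sp] <- vt
    }
    methods::new("NestSplit", assignment = assignment,
                 calibNests = ctab, validNests = vtab,
                 seed = as.integer(seed))
}

# First subset (as a logical index) of `sizes` summing to `target`, found by
# depth-first backtracking; sizes arrive pre-shuffled so the solution is
# random. NULL when no subset exists.
.subsetSum <- function(sizes, target) {
    n <- length(sizes)
    rec <- function(i, left, picked) {
        if (left == 0L) return(picked)
        if (i > n || left < 0L) return(NULL)
        if (sum(sizes[i:n]) < left) return(NULL)
        with <- rec(i + 1L, left - sizes[i], c(picked, i))
        if (!is.null(with)) return(with)
        rec(i + 1L, left, picked)
    }
    idx <- rec(1L, as.integer(target), integer())
    if (is.null(idx) && target != 0L) return(NULL)
    out <- logical(n); out[idx] <- TRUE
    out
}

#' Subset a collection by split side
#'
#' @param x a [SpectraSet-class].
#' @param split a [NestSplit-class].
#' @param side `"calibration"` or `"validation"`.
#' @return the subsetted [SpectraSet-class].
#' @export
splitSubset <- function(x, split, side = c("calibration", "validation")) {
    side <- match.arg(side)
    cd <- specimenData(x)
    a <- split@assignment[cd$nest_id]
    if (anyNA(a)) .valErr("split does not cover every nest in the collection")
    x[, which(a == side)]
}

setMethod("show", "NestSplit", function(object) {
    cat("NestSplit:", sum(object@assignment == "calibration"),
        "calibration /", sum(object@assignment == "validation"),
        "validation nests (seed", object@seed, ")\n")
})
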