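# Hierarchical synthetic NIR collections with known ground truth. The
# generator mimics the structure of a nest-based multi-species survey:
# species share one smooth reflectance baseline and differ only through a
# set of Gaussian absorption bands whose depths scale with a single
# separation parameter delta.

# Smooth shared baseline: a sigmoidal rise through the visible into the NIR
# plateau with two broad water-absorption dips. Values stay well inside
# (0, 1) on the 350-2,500 nm range.
.baselineCurve <- function(w) {
    0.15 + 0.35 / (1 + exp(-(w - 1100) / 300)) -
        0.05 * exp(-((w - 1450) / 60)^2) -
        0.08 * exp(-((w - 1940) / 80)^2)
}

# Deterministic default band sets: one visible (pigmentation) band, two
# CH-overtone-region bands and one combination-region band per species,
# offset so species are distinguishable but heavily overlapping.
.defaultBands <- function(nSpecies, grid) {
    snap <- function(w) grid[which.min(abs(grid - w))]
    lapply(seq_len(nSpecies), function(i) data.frame(
        centre = vapply(c(600 + 40 * i, 1150 + 35 * i,
                          1690 + 30 * i, 2200 + 20 * i), snap, 0),
        width = c(25, 35, 40, 50),
        depth = c(0.015, 0.02, 0.025, 0.02)))
}

#' Configure the hierarchical spectrum generator
#'
#' Defaults emulate a survey of 4 species sampled as 45 nests of 3 workers
#' each, nests grouped into populations, spectra recorded on a 350-2,500 nm
#' grid at 1 nm and averaged over 50 replica scans.
#'
#' @param nSpecies,populationsPerSpecies,nestsPerSpecies,workersPerNest,replicasPerSpecimen
#'   design counts.
#' @param gridFrom,gridTo,gridStep wavelength grid (nm).
#' @param speciesBands optional list of per-species band tables
#'   (`centre`, `width`, `depth`); defaults place bands in the visible and
#'   CH-overtone regions.
#' @param delta separation multiplier on all band depths (0 = no species
#'   signal).
#' @param nestSd,specimenSd standard deviations of the additive nest and
#'   specimen reflectance offsets.
#' @param replicaSd per-wavelength noise sd of a single scan.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSpecies = 4, populationsPerSpecies = 15,
                            nestsPerSpecies = 45, workersPerNest = 3,
                            replicasPerSpecimen = 50,
                            gridFrom = 350, gridTo = 2500, gridStep = 1,
                            speciesBands = NULL, delta = 1,
                            nestSd = 0.01, specimenSd = 0.005,
                            replicaSd = 0.02) {
    grid <- seq(gridFrom, gridTo, by = gridStep)
    if (is.null(speciesBands))
        speciesBands <- .defaultBands(nSpecies, grid)
    tryCatch(methods::new("SyntheticConfig",
        nSpecies = as.integer(nSpecies),
        populationsPerSpecies = as.integer(populationsPerSpecies),
        nestsPerSpecies = as.integer(nestsPerSpecies),
        workersPerNest = as.integer(workersPerNest),
        replicasPerSpecimen = as.integer(replicasPerSpecimen),
        gridFrom = gridFrom, gridTo = gridTo, gridStep = gridStep,
        speciesBands = speciesBands, delta = delta,
        nestSd = nestSd, specimenSd = specimenSd, replicaSd = replicaSd),
        error = function(e) .valErr(conditionMessage(e)))
}

#' Noise-free expected spectrum of one species
#'
#' @param cfg a [SyntheticConfig-class].
#' @param species species index (1-based).
#' @return numeric reflectance on the config grid.
#' @export
speciesMeanSpectrum <- function(cfg, species) {
    grid <- seq(cfg@gridFrom, cfg@gridTo, by = cfg@gridStep)
    b <- cfg@speciesBands[[species]]
    dips <- rowSums(vapply(seq_len(nrow(b)), function(j)
        b$depth[j] * exp(-((grid - b$centre[j]) / b$width[j])^2 / 2),
        numeric(length(grid))))
    .baselineCurve(grid) - cfg@delta * dips
}

#' Generate a synthetic spectral collection
#'
#' Each specimen's spectrum is its species' expected curve plus a
#' nest-level offset, a specimen-level offset (both additive Gaussian
#' scalars), and replica-averaged per-wavelength Gaussian noise with
#' standard deviation `replicaSd / sqrt(replicasPerSpecimen)` — the exact
#' distribution of the mean of that many independent noisy scans. The
#' returned collection is unlabelled; the ground truth comes back as a
#' separate table to be joined with [truthJoin()].
#'
#' @param cfg a [SyntheticConfig-class].
#' @param seed integer; the collection is fully reproducible from it.
#' @return list with `spectra` (an unlabelled [SpectraSet-class]) and
#'   `truth` (data.frame `specimen_id`, `nest_id`, `population_id`,
#'   `species`).
#' @examples
#' cfg <- syntheticConfig(nestsPerSpecies = 6, populationsPerSpecies = 3,
#'                        gridFrom = 500, gridTo = 2300, gridStep = 60)
#' gen <- generateSpectra(cfg, seed = 1)
#' labelled <- truthJoin(gen$spectra, gen$truth)
#' @export
generateSpectra <- function(cfg, seed = 1) {
    set.seed(as.integer(seed))
    grid <- seq(cfg@gridFrom, cfg@gridTo, by = cfg@gridStep)
    p <- length(grid)
    nestsPerPop <- ceiling(cfg@nestsPerSpecies / cfg@populationsPerSpecies)
    meta <- list(); cols <- list()
    for (s in seq_len(cfg@nSpecies)) {
        spName <- paste0("sp", s)
        mu <- speciesMeanSpectrum(cfg, s)
        for (nst in seq_len(cfg@nestsPerSpecies)) {
            nestId <- sprintf("%s_nest%02d", spName, nst)
            popId <- sprintf("%s_pop%02d", spName,
                             ceiling(nst / nestsPerPop))
            nestOff <- stats::rnorm(1L, 0, cfg@nestSd)
            for (wk in seq_len(cfg@workersPerNest)) {
                id <- sprintf("%s_w%d", nestId, wk)
                specOff <- stats::rnorm(1L, 0, cfg@specimenSd)
                noise <- stats::rnorm(p, 0,
                    cfg@replicaSd / sqrt(cfg@replicasPerSpecimen))
                cols[[id]] <- mu + nestOff + specOff + noise
                meta[[id]] <- data.frame(
                    specimen_id = id, nest_id = nestId,
                    population_id = popId, species = spName,
                    stringsAsFactors = FALSE)
            }
        }
    }
    truth <- do.call(rbind, c(meta, make.row.names = FALSE))
    refl <- do.call(cbind, cols)
    unlabelled <- truth
    unlabelled$species <- NA_character_
    list(spectra = SpectraSet(refl, grid, unlabelled), truth = truth)
}

#' Join ground-truth species labels onto a collection
#'
#' @param x a [SpectraSet-class].
#' @param truth data.frame with `specimen_id` and `species`.
#' @return the labelled [SpectraSet-class]. Specimens missing from the
#'   truth table raise an error naming the first orphans.
#' @export
truthJoin <- function(x, truth) {
    cd <- specimenData(x)
    idx <- match(cd$specimen_id, truth$specimen_id)
    if (anyNA(idx))
        .valErr(paste0("specimens missing from truth table: ",
            paste(utils::head(cd$specimen_id[is.na(idx)], 5L), collapse = ", ")))
    tryCatch({
        colData(x)$species <- as.character(truth$species[idx])
        methods::validObject(x)
        x
    }, error = function(e) .valErr(conditionMessage(e)))
}

#' Simulate replica scans of one specimen
#'
#' Materialises `n` noisy scans of a base spectrum (additive iid Gaussian
#' per wavelength), e.g. to study how replica averaging shrinks noise.
#'
#' @param base a [Spectrum-class] to perturb.
#' @param n number of replicas.
#' @param sd per-wavelength noise standard deviation.
#' @param seed integer seed.
#' @return list of [Spectrum-class] replicas.
#' @export
simulateReplicas <- function(base, n = 50, sd = 0.02, seed = 1) {
    set.seed(as.integer(seed))
    lapply(seq_len(n), function(i)
        Spectrum(base@specimenId, base@nestId, base@populationId,
                 base@species, base@wavelengths,
                 base@reflectance + stats::rnorm(length(base@wavelengths), 0, sd)))
}
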