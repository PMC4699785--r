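#' Construct a SpectraSet
#'
#' @param reflectance numeric matrix, wavelengths in rows and specimens in
#'   columns (a specimens-in-rows matrix is accepted when unambiguous from
#'   the grid length and transposed).
#' @param wavelengths numeric grid in nm, strictly increasing.
#' @param specimenData data.frame or DataFrame with columns `specimen_id`,
#'   `nest_id`, `population_id` and optionally `species` (NA allowed).
#'
#' @return A [SpectraSet-class].
#' @examples
#' se <- SpectraSet(matrix(c(0.1, 0.2, 0.3), nrow = 3), c(500, 501, 502),
#'     data.frame(specimen_id = "a", nest_id = "n1", population_id = "p1",
#'                species = "sp1"))
#' wavelengths(se)
#' @export
SpectraSet <- function(reflectance, wavelengths, specimenData) {
    reflectance <- as.matrix(reflectance)
    specimenData <- as.data.frame(specimenData)
    if (!"species" %in% colnames(specimenData)) specimenData$species <- NA_character_
    if (nrow(reflectance) != length(wavelengths)) {
        if (ncol(reflectance) == length(wavelengths))
            reflectance <- t(reflectance)
        else .valErr("reflectance dimensions do not match the wavelength grid")
    }
    if (ncol(reflectance) != nrow(specimenData))
        .valErr("specimenData must have one row per specimen")
    specimenData$species <- as.character(specimenData$species)
    specimenData$species[!is.na(specimenData$species) &
                         !nzchar(specimenData$species)] <- NA_character_
    dimnames(reflectance) <- list(NULL, as.character(specimenData$specimen_id))
    se <- SummarizedExperiment(
        assays = SimpleList(reflectance = reflectance),
        rowData = DataFrame(wavelength = as.numeric(wavelengths)),
        colData = DataFrame(specimenData, row.names = specimenData$specimen_id)
    )
    tryCatch(methods::new("SpectraSet", se),
             error = function(e) .valErr(conditionMessage(e)))
}

#' Construct a single Spectrum
#'
#' @param specimenId,nestId,populationId,species metadata strings
#'   (`species` may be `NA`).
#' @param wavelengths,reflectance the grid and reflectance values.
#' @return A [Spectrum-class].
#' @export
Spectrum <- function(specimenId, nestId, populationId, species = NA_character_,
                     wavelengths, reflectance) {
    tryCatch(methods::new("Spectrum",
        specimenId = as.character(specimenId), nestId = as.character(nestId),
        populationId = as.character(populationId),
        species = as.character(species),
        wavelengths = as.numeric(wavelengths),
        reflectance = as.numeric(reflectance)),
        error = function(e) .valErr(conditionMessage(e)))
}

#' Wavelength grid of a collection
#' @param x a [SpectraSet-class] or [Spectrum-class].
#' @return numeric vector of wavelengths (nm).
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' Reflectance matrix (wavelengths x specimens)
#' @param x a [SpectraSet-class] or [Spectrum-class].
#' @return numeric matrix (or vector for a single spectrum).
#' @rdname reflectance
#' @export
setMethod("reflectance", "SpectraSet", function(x) assay(x, "reflectance"))

#' @rdname reflectance
#' @export
setMethod("reflectance", "Spectrum", function(x) x@reflectance)

#' Specimen metadata
#' @param x a [SpectraSet-class].
#' @return a data.frame with specimen_id, nest_id, population_id, species.
#' @rdname specimenData
#' @export
setMethod("specimenData", "SpectraSet",
    function(x) as.data.frame(colData(x)))

setMethod("show", "SpectraSet", function(object) {
    w <- wavelengths(object)
    sp <- specimenData(object)$species
    cat("SpectraSet:", ncol(object), "specimens,", nrow(object),
        "wavelengths")
    if (length(w)) cat(sprintf(" (%g-%g nm)", min(w), max(w)))
    cat("\n  nests:", length(unique(specimenData(object)$nest_id)),
        " populations:", length(unique(specimenData(object)$population_id)),
        "\n  species:", if (all(is.na(sp))) "<unlabelled>" else
            paste(sort(unique(stats::na.omit(sp))), collapse = ", "), "\n")
})

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum", object@specimenId, "(nest", object@nestId, "):",
        length(object@wavelengths), "wavelengths\n")
})

#' Extract one specimen as a Spectrum
#' @param x a [SpectraSet-class].
#' @param i specimen index or specimen_id.
#' @return a [Spectrum-class].
#' @export
getSpectrum <- function(x, i) {
    cd <- specimenData(x)
    if (is.character(i)) i <- match(i, cd$specimen_id)
    if (is.na(i) || i < 1L || i > nrow(cd)) .valErr("specimen not found")
    Spectrum(cd$specimen_id[i], cd$nest_id[i], cd$population_id[i],
             cd$species[i], wavelengths(x), reflectance(x)[, i])
}

.metaCols <- c("specimen_id", "nest_id", "population_id", "species")

#' Read a wide-format spectral table
#'
#' Expects the metadata columns `specimen_id`, `nest_id`, `population_id`,
#' `species` (empty = unknown) followed by one numeric column per
#' wavelength, the header naming the nm value.
#'
#' @param path file to read.
#' @param sep field separator (default comma).
#' @return A validated [SpectraSet-class]; the grid is inferred from the
#'   header.
#' @export
readSpectra <- function(path, sep = ",") {
    if (!file.exists(path)) .ioErr(paste("file not found:", path))
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, fill = FALSE,
                          colClasses = "character"),
        error = function(e) .fmtErr(paste("cannot parse", path, ":",
                                          conditionMessage(e))))
    miss <- setdiff(.metaCols, colnames(df))
    if (length(miss))
        .fmtErr(paste("missing metadata columns:", paste(miss, collapse = ", ")))
    wcols <- setdiff(colnames(df), .metaCols)
    w <- suppressWarnings(as.numeric(wcols))
    if (length(wcols) && any(is.na(w)))
        .fmtErr("wavelength header entries must be numeric")
    vals <- matrix(as.numeric(as.matrix(df[, wcols, drop = FALSE])),
                   nrow = nrow(df), ncol = length(wcols))
    if (anyNA(vals)) .fmtErr("non-numeric or missing reflectance values")
    if (length(w) > 1L && any(diff(w) <= 0))
        .valErr("wavelength grid in header is not strictly increasing")
    SpectraSet(t(vals), w, df[, .metaCols])
}

#' Write a collection as a wide-format delimited table
#'
#' Metadata columns first, then one column per wavelength. Values are
#' written with 17 significant digits so a read/write round trip is
#' bit-identical.
#'
#' @param x a [SpectraSet-class].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path, sep = ",") {
    stopifnot(methods::is(x, "SpectraSet"))
    cd <- specimenData(x)
    cd$species[is.na(cd$species)] <- ""
    vals <- t(reflectance(x))
    header <- c(.metaCols, format(wavelengths(x), trim = TRUE, digits = 15))
    lines <- paste(header, collapse = sep)
    if (nrow(cd)) {
        num <- apply(vals, 1L, function(r)
            paste(sprintf("%.17g", r), collapse = sep))
        meta <- apply(cd[, .metaCols], 1L, paste, collapse = sep)
        lines <- c(lines, if (ncol(vals)) paste(meta, num, sep = sep) else meta)
    }
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) .ioErr(paste("cannot write", path))
    invisible(path)
}

#' Average replicate scans of one specimen
#'
#' Repeated scans of the same specimen are averaged pointwise to increase
#' the signal-to-noise ratio; the standard deviation of independent
#' per-wavelength noise shrinks by `1/sqrt(n)` over `n` replicas.
#'
#' @param scans list of [Spectrum-class] objects sharing specimen and grid.
#' @return a single [Spectrum-class] with metadata from the first scan.
#' @export
averageReplicas <- function(scans) {
    if (!length(scans)) .valErr("no scans to average")
    ids <- vapply(scans, function(s) s@specimenId, "")
    if (length(unique(ids)) != 1L)
        .valErr("scans mix specimen ids; average one specimen at a time")
    grid <- scans[[1L]]@wavelengths
    for (s in scans[-1L])
        if (!identical(s@wavelengths, grid))
            .valErr("scans do not share a wavelength grid")
    m <- vapply(scans, function(s) s@reflectance, numeric(length(grid)))
    first <- scans[[1L]]
    Spectrum(first@specimenId, first@nestId, first@populationId,
             first@species, grid, rowMeans(as.matrix(m)))
}
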