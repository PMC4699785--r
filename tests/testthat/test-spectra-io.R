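test_that("wide-format tables parse with the grid inferred from the header", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "specimen_id,nest_id,population_id,species,500,501,502",
        "a1,na,pa,spA,0.1,0.2,0.3",
        "b1,nb,pb,,0.4,0.5,0.6"), path)
    x <- readSpectra(path)
    expect_s4_class(x, "SpectraSet")
    expect_equal(ncol(x), 2L)
    expect_equal(wavelengths(x), c(500, 501, 502))
    expect_equal(unname(reflectance(x)[, "a1"]), c(0.1, 0.2, 0.3))
    expect_true(is.na(specimenData(x)$species[2]))  # empty field = unknown
})

test_that("structural violations are rejected on read", {
    path <- withr::local_tempfile(fileext = ".csv")
    # same nest under two populations
    writeLines(c(
        "specimen_id,nest_id,population_id,species,500,501",
        "a1,na,pa,spA,0.1,0.2",
        "a2,na,pb,spA,0.3,0.4"), path)
    expect_error(readSpectra(path), class = "nirsova_validation_error")

    # duplicate specimen id
    writeLines(c(
        "specimen_id,nest_id,population_id,species,500,501",
        "a1,na,pa,spA,0.1,0.2",
        "a1,na,pa,spA,0.3,0.4"), path)
    expect_error(readSpectra(path), class = "nirsova_validation_error")

    # non-monotone grid
    writeLines(c(
        "specimen_id,nest_id,population_id,species,502,501",
        "a1,na,pa,spA,0.1,0.2"), path)
    expect_error(readSpectra(path), class = "nirsova_validation_error")

    # ragged row
    writeLines(c(
        "specimen_id,nest_id,population_id,species,500,501",
        "a1,na,pa,spA,0.1"), path)
    expect_error(readSpectra(path), class = "nirsova_format_error")

    expect_error(readSpectra(file.path(tempdir(), "no-such-file.csv")),
                 class = "nirsova_io_error")
})

test_that("write/read round trip is bit-identical including metadata", {
    x <- smallCollection(seed = 11)
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(x, path)
    y <- readSpectra(path)
    expect_identical(reflectance(y), reflectance(x))
    expect_identical(wavelengths(y), wavelengths(x))
    expect_identical(specimenData(y), specimenData(x))
})

test_that("an empty collection writes a header-only file", {
    x <- SpectraSet(matrix(numeric(), nrow = 3, ncol = 0), c(500, 501, 502),
                    data.frame(specimen_id = character(),
                               nest_id = character(),
                               population_id = character(),
                               species = character()))
    path <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(x, path)
    expect_length(readLines(path), 1L)
    expect_equal(ncol(readSpectra(path)), 0L)
})

test_that("replica averaging is the pointwise mean with metadata preserved", {
    s1 <- Spectrum("s", "n", "p", "spA", c(500, 501), c(0, 2))
    s2 <- Spectrum("s", "n", "p", "spA", c(500, 501), c(2, 0))
    avg <- averageReplicas(list(s1, s2))
    expect_equal(reflectance(avg), c(1, 1))
    expect_equal(avg@nestId, "n")

    # mean of identical scans is that scan
    same <- averageReplicas(rep(list(s1), 50))
    expect_equal(reflectance(same), reflectance(s1))

    s3 <- Spectrum("other", "n", "p", "spA", c(500, 501), c(1, 1))
    expect_error(averageReplicas(list(s1, s3)),
                 class = "nirsova_validation_error")
    expect_error(averageReplicas(list()), class = "nirsova_validation_error")
})

test_that("averaging n noisy replicas shrinks noise variance by about 1/n", {
    base <- Spectrum("s", "n", "p", NA, seq(500, 2000, by = 5),
                     rep(0.5, 301))
    scans <- simulateReplicas(base, n = 50, sd = 0.02, seed = 123)
    avg <- averageReplicas(scans)
    empVar <- stats::var(reflectance(avg) - reflectance(base))
    expect_lt(abs(empVar - 0.02^2 / 50) / (0.02^2 / 50), 0.25)
})

test_that("averaging commutes with wavelength trimming", {
    grid <- seq(400, 2400, by = 100)
    set.seed(5)
    scans <- lapply(1:4, function(i)
        Spectrum("s", "n", "p", NA, grid, runif(length(grid))))
    avg <- averageReplicas(scans)
    keep <- grid >= 500 & grid <= 2300
    trimmedScanMeans <- rowMeans(vapply(scans,
        function(s) reflectance(s)[keep], numeric(sum(keep))))
    expect_equal(reflectance(avg)[keep], trimmedScanMeans)
})
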