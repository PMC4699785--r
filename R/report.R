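#' Run the full one-vs-all identification routine
#'
#' Repeats the one-vs-all task for every species in turn (each species is
#' Class 1 exactly once), runs the exclusion search and nestmate
#' propagation for each, and assembles a summary table: individuals correct
#' and incorrect prior to exclusion, the exclusion range (or a failure
#' marker), individuals correct and incorrect after exclusion, individuals
#' identified after nestmate propagation, and nests identified — each with
#' percentages against the validation-set denominators — plus a totals row.
#'
#' Specimens identified by more than one task are recorded in the
#' `conflicts` slot (nests are assumed monospecific, so a conflict signals
#' a modelling problem, and it is reported rather than resolved).
#' Validation specimens identified by no task are listed as unclassified:
#' they would need a method other than NIRS.
#'
#' @param x labelled [SpectraSet-class].
#' @param split a [NestSplit-class].
#' @param spec a [BackendSpec-class] applied to every task.
#' @param species species order for the report (default: sorted labels).
#' @param seed base seed; task i uses `seed + i - 1`.
#' @return an [IdentificationReport-class].
#' @export
runIdentification <- function(x, split, spec = backendSpec("pls"),
                              species = NULL, seed = 1) {
    cd <- specimenData(x)
    if (is.null(species)) species <- sort(unique(cd$species))
    val <- splitSubset(x, split, "validation")
    vd <- specimenData(val)

    runs <- vector("list", length(species))
    names(runs) <- species
    rows <- list()
    for (i in seq_along(species)) {
        sp <- species[[i]]
        task <- runOneVsAll(x, split, sp, spec, seed = seed + i - 1L)
        outcome <- exclusionSearch(task$records, task$spec@threshold,
                                   cap = task$spec@classCodes)
        records <- applyExclusion(task$records, outcome)
        identified <- if (outcome@status == "success")
            nestmatePropagate(records, outcome) else character()
        runs[[sp]] <- methods::new("OvaRun",
            class1 = sp, class2 = setdiff(species, sp), spec = task$spec,
            settings = task$settings, records = records, outcome = outcome,
            identified = identified)

        n1 <- sum(records$true_class == 1L)          # Class-1 validation size
        nNests1 <- length(unique(records$nest_id[records$true_class == 1L]))
        correctPrior <- sum(records$true_class == 1L & records$assigned_class == 1L)
        ok <- outcome@status == "success"
        correctAfter <- if (ok) outcome@retainedTruePositives else 0L
        nestsOK <- if (ok) length(unique(
            records$nest_id[records$true_class == 1L &
                            records$assigned_class == 1L & !records$excluded]))
            else 0L
        rows[[sp]] <- data.frame(
            class1 = sp,
            class2 = paste(setdiff(species, sp), collapse = "/"),
            n_variables = nrow(x),
            settings = paste(names(task$settings), unlist(task$settings),
                             sep = "=", collapse = ";"),
            correct_prior = correctPrior,
            incorrect_prior = n1 - correctPrior,
            exclusion_range = if (!ok) "-" else if (is.na(outcome@lo)) "none"
                else sprintf("%.2f-%.2f", outcome@lo, outcome@hi),
            correct_after = correctAfter,
            incorrect_after = if (ok) outcome@falsePositivesRemaining else 0L,
            identified_nestmates = length(identified),
            nests_correct = nestsOK,
            n_class1 = n1,
            n_class1_nests = nNests1,
            stringsAsFactors = FALSE)
    }
    table <- do.call(rbind, c(rows, make.row.names = FALSE))
    pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
    table$correct_prior_pct <- pct(table$correct_prior, table$n_class1)
    table$correct_after_pct <- pct(table$correct_after, table$n_class1)
    table$identified_pct <- pct(table$identified_nestmates, table$n_class1)
    table$nests_correct_pct <- pct(table$nests_correct, table$n_class1_nests)

    total <- data.frame(
        class1 = "Total", class2 = "", n_variables = nrow(x), settings = "",
        correct_prior = sum(table$correct_prior),
        incorrect_prior = sum(table$incorrect_prior),
        exclusion_range = "",
        correct_after = sum(table$correct_after),
        incorrect_after = sum(table$incorrect_after),
        identified_nestmates = sum(table$identified_nestmates),
        nests_correct = sum(table$nests_correct),
        n_class1 = sum(table$n_class1),
        n_class1_nests = sum(table$n_class1_nests),
        correct_prior_pct = pct(sum(table$correct_prior), sum(table$n_class1)),
        correct_after_pct = pct(sum(table$correct_after), sum(table$n_class1)),
        identified_pct = pct(sum(table$identified_nestmates), sum(table$n_class1)),
        nests_correct_pct = pct(sum(table$nests_correct), sum(table$n_class1_nests)),
        stringsAsFactors = FALSE)
    table <- rbind(table, total)

    idTally <- unlist(lapply(species, function(sp) runs[[sp]]@identified))
    dup <- unique(idTally[duplicated(idTally)])
    conflicts <- if (length(dup)) {
        do.call(rbind, lapply(dup, function(id) data.frame(
            specimen_id = id,
            species = paste(species[vapply(species, function(sp)
                id %in% runs[[sp]]@identified, TRUE)], collapse = "/"),
            stringsAsFactors = FALSE)))
    } else data.frame(specimen_id = character(), species = character(),
                      stringsAsFactors = FALSE)
    unclassified <- setdiff(vd$specimen_id, unique(idTally))

    methods::new("IdentificationReport", table = table, runs = runs,
                 conflicts = conflicts, unclassified = unclassified)
}

setMethod("show", "IdentificationReport", function(object) {
    t <- object@table
    cat("IdentificationReport —", nrow(t) - 1L, "one-vs-all tasks\n")
    disp <- data.frame(
        Class1 = t$class1,
        `correct prior` = sprintf("%d (%.1f%%)", t$correct_prior,
                                  t$correct_prior_pct),
        `exclusion` = t$exclusion_range,
        `correct after` = sprintf("%d (%.1f%%)", t$correct_after,
                                  t$correct_after_pct),
        `identified (+nestmates)` = sprintf("%d (%.1f%%)",
            t$identified_nestmates, t$identified_pct),
        `nests` = sprintf("%d (%.1f%%)", t$nests_correct,
                          t$nests_correct_pct),
        check.names = FALSE)
    print(disp, row.names = FALSE)
    if (nrow(object@conflicts))
        cat("Conflicting identifications:", nrow(object@conflicts), "\n")
    cat("Unclassifiable by NIRS:", length(object@unclassified),
        "validation specimens\n")
})

#' Write an identification report to disk
#'
#' Emits the summary table as CSV, the full report (schema-versioned, with
#' raw counts so every percentage is re-derivable) as JSON, and one
#' prediction-record CSV per task.
#'
#' @param report an [IdentificationReport-class].
#' @param dir output directory (created if needed).
#' @param seed,configHash provenance recorded in the JSON.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(report, dir, seed = NULL, configHash = NULL) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        .ioErr(paste("cannot create", dir))
    utils::write.csv(report@table, file.path(dir, "report.csv"),
                     row.names = FALSE)
    for (sp in names(report@runs))
        utils::write.csv(report@runs[[sp]]@records,
            file.path(dir, paste0("predictions_", gsub("[^A-Za-z0-9_.-]", "_", sp), ".csv")),
            row.names = FALSE)
    payload <- list(
        schema = "nirsova-report/1",
        seed = seed, config_hash = configHash,
        table = report@table,
        conflicts = report@conflicts,
        unclassified = report@unclassified,
        outcomes = lapply(report@runs, function(r) list(
            class1 = r@class1, status = r@outcome@status,
            lo = r@outcome@lo, hi = r@outcome@hi,
            n_steps = r@outcome@nSteps,
            retained_true_positives = r@outcome@retainedTruePositives,
            excluded_class1 = r@outcome@excludedClass1,
            false_positives_remaining = r@outcome@falsePositivesRemaining,
            settings = r@settings)))
    jsonlite::write_json(payload, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(dir)
}
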