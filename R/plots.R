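#' Exclusion plot for one task
#'
#' Shows, per widening step of the symmetric exclusion interval, how many
#' Class-2 validation specimens remain falsely inside Class 1 and how many
#' specimens have been excluded; the vertical line marks the step at which
#' all remaining specimens are correctly classified.
#'
#' @param records prediction records of a task.
#' @param threshold decision threshold.
#' @param halfStep widening increment per side.
#' @param cap class codes bounding the search.
#' @param main plot title.
#' @return invisibly, the data.frame of per-step counts.
#' @export
plotExclusion <- function(records, threshold, halfStep = 0.05,
                          cap = c(1, 2), main = "Exclusion of false positives") {
    maxSteps <- ceiling((threshold - cap[1L]) / halfStep)
    isFP <- records$true_class == 2L & records$assigned_class == 1L
    steps <- 0:maxSteps
    counts <- t(vapply(steps, function(k) {
        if (k == 0L) excl <- rep(FALSE, nrow(records))
        else {
            lo <- max(threshold - k * halfStep, cap[1L])
            hi <- min(threshold + k * halfStep, cap[2L])
            excl <- records$value >= lo & records$value <= hi
        }
        c(fp = sum(isFP & !excl), excluded = sum(excl))
    }, c(fp = 0, excluded = 0)))
    df <- data.frame(step = steps, range = 2 * steps * halfStep,
                     fp_remaining = counts[, "fp"],
                     excluded = counts[, "excluded"])
    graphics::plot(df$range, df$fp_remaining, type = "b", pch = 19,
                   xlab = "Width of exclusion range",
                   ylab = "Count", main = main,
                   ylim = c(0, max(df$excluded, df$fp_remaining, 1)))
    graphics::lines(df$range, df$excluded, type = "b", pch = 1, lty = 2)
    done <- df$range[which(df$fp_remaining == 0)[1L]]
    if (!is.na(done)) graphics::abline(v = done, col = "grey40", lty = 3)
    graphics::legend("topright", c("false positives remaining", "excluded"),
                     pch = c(19, 1), lty = c(1, 2), bty = "n")
    invisible(df)
}

#' Strategy elaboration-time comparison plot
#'
#' Hours of calibration-model elaboration for an exhaustive search under
#' each strategy, against the number of classes (log-scaled time axis).
#'
#' @param costs data.frame from [strategyCostTable()].
#' @param main plot title.
#' @return invisibly, `costs`.
#' @export
plotStrategyCosts <- function(costs, main = "Time needed for model elaboration") {
    strategies <- c("one_vs_all", "binary_A", "binary_B")
    cols <- c(one_vs_all = "black", binary_A = "firebrick",
              binary_B = "steelblue")
    graphics::plot(range(costs$classes), range(costs$hours), type = "n",
                   log = "y", xlab = "Number of classes", ylab = "Hours",
                   main = main)
    for (s in strategies) {
        sub <- costs[costs$strategy == s, ]
        graphics::lines(sub$classes, sub$hours, type = "b", pch = 19,
                        col = cols[[s]])
    }
    graphics::legend("topleft", legend = strategies, col = cols[strategies],
                     pch = 19, lty = 1, bty = "n")
    invisible(costs)
}
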