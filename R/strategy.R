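# Exhaustive-search cost calculus for the three multi-class-reduction
# strategies. An exhaustive search elaborates the optimal calibration model
# for every decision step a strategy could ever need, so its cost is the
# number of distinct two-group comparisons times the per-model time.

.checkClasses <- function(c) {
    if (length(c) != 1L || !is.finite(c) || c != round(c) || c < 2)
        .domErr("class count must be an integer >= 2")
    as.integer(c)
}

# Canonical key for an unordered two-group comparison.
.cmpKey <- function(g1, g2) {
    a <- paste(sort(g1), collapse = ",")
    b <- paste(sort(g2), collapse = ",")
    if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
}

.cmpList <- function(keys) {
    lapply(sort(unique(keys)), function(k) {
        parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
        list(group1 = strsplit(parts[1L], ",", fixed = TRUE)[[1L]],
             group2 = strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    })
}

#' Model counts for exhaustive strategy searches
#'
#' `stepsOneVsAll(c)` gives the number of calibration models for the
#' one-vs-all strategy: `c - 1` for two classes (one model separates both),
#' otherwise `c`. `stepsBinaryA(c)` is the closed form
#' `2^(c-1) * c - c(c+1)/2` for the sequential peel-off strategy
#' (every subset of at least two classes, one class split off at a time).
#' `stepsBinaryB(c)` counts the distinct comparisons arising in
#' balanced-halving decision trees, obtained by enumeration.
#'
#' @param c number of classes (>= 2).
#' @return integer model count.
#' @examples
#' stepsOneVsAll(4)  # 4
#' stepsBinaryA(4)   # 22
#' stepsBinaryB(4)   # 9
#' @export
stepsOneVsAll <- function(c) {
    c <- .checkClasses(c)
    if (c == 2L) c - 1L else c
}

#' @rdname stepsOneVsAll
#' @export
stepsBinaryA <- function(c) {
    c <- .checkClasses(c)
    as.integer(2^(c - 1) * c - c * (c + 1) / 2)
}

#' @rdname stepsOneVsAll
#' @export
stepsBinaryB <- function(c) {
    c <- .checkClasses(c)
    length(enumerateModelsBinaryB(c))
}

#' Enumerate the distinct comparisons of a strategy
#'
#' For the sequential peel-off strategy (type A) the comparisons are
#' `{x}` versus `S \ {x}` over every subset `S` of at least two classes and
#' every `x` in `S`, deduplicated as unordered comparisons. For the
#' balanced-halving strategy (type B) every subset whose size arises by
#' repeatedly halving the full class count (sizes `s -> ceil(s/2), floor(s/2)`
#' down to 2) is partitioned in every way into parts of sizes `ceil(s/2)` and
#' `floor(s/2)`.
#'
#' @param c number of classes (>= 2).
#' @return list of comparisons, each a `list(group1, group2)` of disjoint
#'   non-empty class-label sets; the list is deduplicated and ordered by a
#'   canonical key.
#' @export
enumerateModelsBinaryA <- function(c) {
    c <- .checkClasses(c)
    classes <- as.character(seq_len(c))
    keys <- character()
    for (size in 2:c) {
        subsets <- utils::combn(classes, size, simplify = FALSE)
        for (S in subsets)
            for (x in S)
                keys <- c(keys, .cmpKey(x, setdiff(S, x)))
    }
    .cmpList(keys)
}

#' @rdname enumerateModelsBinaryA
#' @export
enumerateModelsBinaryB <- function(c) {
    c <- .checkClasses(c)
    classes <- as.character(seq_len(c))
    # closure of {c} under s -> {ceiling(s/2), floor(s/2)}, keeping s >= 2
    sizes <- integer(); queue <- c
    while (length(queue)) {
        s <- queue[[1L]]; queue <- queue[-1L]
        if (s < 2L || s %in% sizes) next
        sizes <- c(sizes, s)
        queue <- c(queue, ceiling(s / 2), floor(s / 2))
    }
    keys <- character()
    for (s in sizes) {
        v1 <- ceiling(s / 2); v2 <- s - v1
        for (S in utils::combn(classes, s, simplify = FALSE)) {
            if (v1 == v2) {
                # fix S[1] in group1 so each unordered halving appears once
                rest <- S[-1L]
                picks <- utils::combn(rest, v1 - 1L, simplify = FALSE)
                for (p in picks) {
                    g1 <- c(S[1L], p)
                    keys <- c(keys, .cmpKey(g1, setdiff(S, g1)))
                }
            } else {
                for (g1 in utils::combn(S, v1, simplify = FALSE))
                    keys <- c(keys, .cmpKey(g1, setdiff(S, g1)))
            }
        }
    }
    .cmpList(keys)
}

# Round half away from zero, as printed results do.
.roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Elaboration time for an exhaustive strategy search
#'
#' Multiplies the strategy's model count by the per-model elaboration time.
#' The default of 4/3 h (80 min, printed as 1.33 h) is an empirical value
#' for elaborating one calibration model including the evaluation of about a
#' dozen PLS factor settings.
#'
#' @param c number of classes (>= 2).
#' @param strategy `"one_vs_all"`, `"binary_A"` or `"binary_B"`.
#' @param perModelHours hours per calibration model (> 0).
#' @return a one-row data.frame with columns `classes`, `strategy`,
#'   `models`, `hours` (exact) and `hoursDisplay` (rounded half-up to one
#'   decimal, the convention used in print).
#' @examples
#' elaborationHours(4, "one_vs_all")$hoursDisplay  # 5.3
#' elaborationHours(7, "binary_A")$hoursDisplay    # 560
#' @export
elaborationHours <- function(c, strategy = c("one_vs_all", "binary_A", "binary_B"),
                             perModelHours = 4 / 3) {
    strategy <- match.arg(strategy)
    if (perModelHours <= 0) .domErr("perModelHours must be > 0")
    steps <- switch(strategy,
        one_vs_all = stepsOneVsAll(c),
        binary_A = stepsBinaryA(c),
        binary_B = stepsBinaryB(c))
    hours <- steps * perModelHours
    data.frame(classes = as.integer(c), strategy = strategy,
               models = steps, hours = hours,
               hoursDisplay = .roundHalfUp(hours, 1L))
}

#' Strategy cost table over a range of class counts
#'
#' @param cRange integer class counts (each >= 2).
#' @param perModelHours hours per calibration model.
#' @return data.frame with one row per (class count, strategy).
#' @export
strategyCostTable <- function(cRange = 2:7, perModelHours = 4 / 3) {
    rows <- lapply(cRange, function(cc)
        do.call(rbind, lapply(c("one_vs_all", "binary_A", "binary_B"),
            function(s) elaborationHours(cc, s, perModelHours))))
    do.call(rbind, rows)
}
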