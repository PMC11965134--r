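#' @include AllClasses.R
#' @importFrom stats ks.test t.test wilcox.test var.test sd median quantile
#'   pnorm p.adjust
NULL

#' One-sample Kolmogorov-Smirnov normality check
#'
#' KS statistic of the sample against a normal with the sample's own mean
#' and SD (the common software behaviour; estimating the parameters makes
#' the test conservative, which is accepted rather than corrected). The
#' sample is called normal when p >= 0.05.
#'
#' @param values numeric, n >= 4, non-constant
#' @return list(statistic, p.value, normal)
#' @export
ksNormality <- function(values) {
    values <- values[is.finite(values)]
    if (length(values) < 4L)
        stop("degenerate input: need at least 4 values")
    if (stats::sd(values) == 0)
        stop("degenerate input: constant values")
    kt <- suppressWarnings(
        stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    list(statistic = unname(kt$statistic), p.value = kt$p.value,
         normal = kt$p.value >= 0.05)
}

#' Cohen's d from group moments
#'
#' |mean1 - mean2| divided by the pooled SD
#' sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)).
#' Symmetric in group order and scale-invariant.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group moments (n >= 2, SDs not both 0)
#' @return the effect size, a non-negative scalar
#' @examples
#' cohensD(0.060, 0.005, 30, 0.080, 0.009, 24)  # 2.835
#' @export
cohensD <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
    if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
    if (sd1 == 0 && sd2 == 0)
        stop("degenerate input: both SDs are zero")
    pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
    abs(mean1 - mean2) / pooled
}

.fmtMeanSd <- function(x) sprintf("%.3f ± %.3f", mean(x), stats::sd(x))
.fmtMedIqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    sprintf("%.3f (%.3f, %.3f)", q[2], q[1], q[3])
}

#' Two-group comparison with a normality/variance gate
#'
#' Both groups are checked with [ksNormality()] and an F-test for equal
#' variances. When both are normal and the variances compatible, a pooled
#' two-sample t-test is used and the groups summarized as mean +/- SD;
#' otherwise a two-sided Mann-Whitney U test with median (IQR) summaries.
#' Cohen's d is always computed from the group moments.
#'
#' @param low,high numeric vectors, each n >= 4
#' @param parameter label carried into the result
#' @param test "auto" applies the gate; "t" or "mann-whitney" forces a route
#' @param alpha significance level for gate and flag
#' @return a [GroupComparison-class]
#' @export
compareGroups <- function(low, high, parameter = "value",
                          test = c("auto", "t", "mann-whitney"),
                          alpha = 0.05) {
    test <- match.arg(test)
    low <- low[is.finite(low)]; high <- high[is.finite(high)]
    if (length(low) < 4L || length(high) < 4L)
        stop("degenerate input: each group needs at least 4 values")
    constant <- stats::sd(low) == 0 || stats::sd(high) == 0
    if (constant && test != "mann-whitney")
        stop("degenerate input: constant group; only rank tests apply ",
             "(jitter required for parametric route)")
    normP <- c(low = NA_real_, high = NA_real_)
    varP <- NA_real_
    if (test == "auto") {
        normP["low"] <- ksNormality(low)$p.value
        normP["high"] <- ksNormality(high)$p.value
        varP <- stats::var.test(low, high)$p.value
        useT <- all(normP >= alpha) && varP >= alpha
    } else useT <- test == "t"
    if (useT) {
        p <- stats::t.test(low, high, var.equal = TRUE)$p.value
        sumLow <- .fmtMeanSd(low); sumHigh <- .fmtMeanSd(high)
        used <- "t"
    } else {
        p <- suppressWarnings(
            stats::wilcox.test(low, high, exact = NULL,
                               alternative = "two.sided"))$p.value
        sumLow <- .fmtMedIqr(low); sumHigh <- .fmtMedIqr(high)
        used <- "mann-whitney"
    }
    d <- if (constant) NA_real_ else
        cohensD(mean(low), stats::sd(low), length(low),
                mean(high), stats::sd(high), length(high))
    new("GroupComparison", parameter = parameter, summaryLow = sumLow,
        summaryHigh = sumHigh, normalityP = normP, varianceP = varP,
        testUsed = used, pValue = p, cohensD = d,
        significant = is.finite(p) && p < alpha)
}

#' Compare every parameter between grades
#'
#' One gated two-group comparison per quantity (the eight MAD parameters
#' plus ADC), returned both as objects and as a summary table. No
#' multiple-comparison correction is applied by default (exploratory
#' analysis); set `adjust` to a [stats::p.adjust()] method to add adjusted
#' p-values.
#'
#' @param cohort a [MADCohort-class] containing both grades
#' @param adjust "none" (default), or a p.adjust method such as
#'   "bonferroni"/"BH"
#' @return list(comparisons = list of [GroupComparison-class],
#'   table = data.frame with one row per parameter)
#' @export
summarizeComparisons <- function(cohort, adjust = "none") {
    tab <- cohortTable(cohort)
    if (!all(c("low", "high") %in% tab$grade))
        stop("cohort must contain both grades")
    low <- tab[tab$grade == "low", ]
    high <- tab[tab$grade == "high", ]
    cmps <- lapply(.COHORT_PARAM_NAMES, function(nm)
        compareGroups(low[[nm]], high[[nm]], parameter = nm))
    names(cmps) <- .COHORT_PARAM_NAMES
    out <- data.frame(
        parameter = .COHORT_PARAM_NAMES,
        lowGrade = vapply(cmps, slot, character(1), "summaryLow"),
        highGrade = vapply(cmps, slot, character(1), "summaryHigh"),
        test = vapply(cmps, slot, character(1), "testUsed"),
        pValue = vapply(cmps, slot, numeric(1), "pValue"),
        cohensD = vapply(cmps, slot, numeric(1), "cohensD"),
        significant = vapply(cmps, slot, logical(1), "significant"),
        row.names = NULL)
    if (!identical(adjust, "none"))
        out$pAdjusted <- stats::p.adjust(out$pValue, method = adjust)
    list(comparisons = cmps, table = out)
}

#' Clinical characteristics table
#'
#' Counts and percentages per category for the whole cohort and per grade
#' group, plus the age median and range — the standard "Table 1" layout.
#' Percentages are 100 * count / group total, rounded to one decimal.
#'
#' @param metadata data.frame with columns `grade` ("low"/"high") and `age`,
#'   plus any categorical columns named in `categories`
#' @param categories categorical columns to tabulate
#' @return list(age = data.frame, categories = data.frame with columns
#'   characteristic, level, group, n, pct)
#' @export
clinicalSummary <- function(metadata,
                            categories = intersect(c("sex", "whoIsup",
                                                     "tStage"),
                                                   names(metadata))) {
    if (!all(c("grade", "age") %in% names(metadata)))
        stop("metadata must have 'grade' and 'age' columns")
    if (!all(metadata$grade %in% c("low", "high")))
        stop("unknown category in 'grade'")
    groups <- list(all = metadata,
                   low = metadata[metadata$grade == "low", ],
                   high = metadata[metadata$grade == "high", ])
    age <- do.call(rbind, lapply(names(groups), function(g) {
        a <- groups[[g]]$age
        data.frame(group = g, median = stats::median(a),
                   min = min(a), max = max(a))
    }))
    rows <- list()
    for (ch in categories) {
        if (any(is.na(metadata[[ch]])))
            stop("unknown (missing) category value in '", ch, "'")
        levs <- if (is.factor(metadata[[ch]])) levels(metadata[[ch]])
                else sort(unique(as.character(metadata[[ch]])))
        for (g in names(groups)) {
            total <- nrow(groups[[g]])
            for (lv in levs) {
                n <- sum(as.character(groups[[g]][[ch]]) == lv)
                rows[[length(rows) + 1L]] <- data.frame(
                    characteristic = ch, level = lv, group = g, n = n,
                    pct = round(100 * n / total, 1))
            }
        }
    }
    list(age = age, categories = do.call(rbind, rows))
}
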