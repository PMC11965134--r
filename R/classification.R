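#' @include AllClasses.R
#' @importFrom stats plogis glm.fit binomial
NULL

.checkScores <- function(scores, labels) {
    if (length(scores) != length(labels))
        stop("scores and labels must have equal length")
    labels <- as.integer(as.logical(labels))
    if (any(is.na(scores)) || any(is.na(labels)))
        stop("missing values in scores or labels")
    if (length(unique(labels)) < 2L)
        stop("both classes must be present")
    labels
}

## Empirical ROC points for oriented scores (rule: score >= t is positive).
.rocPoints <- function(scores, labels) {
    thr <- sort(unique(scores), decreasing = TRUE)
    pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
    tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
    list(fpr = c(0, fpr), tpr = c(0, tpr), thresholds = c(Inf, thr))
}

.trapezoidAUC <- function(fpr, tpr) {
    n <- length(fpr)
    sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
}

#' Empirical ROC curve with trapezoid AUC
#'
#' All distinct score thresholds are scanned (rule: score at or above the
#' threshold calls the positive, high-grade class). The orientation is
#' chosen automatically so the AUC is at least 0.5, with the direction
#' recorded in `higherIsPositive`.
#'
#' @param scores numeric per-subject scores
#' @param labels logical or 0/1; TRUE/1 marks the positive (high-grade) class
#' @param name label carried into the result
#' @return a [ROCResult-class] (CI and operating-point slots left NA; see
#'   [aucCI()] and [youdenPoint()] or [rocAnalysis()])
#' @export
rocCurve <- function(scores, labels, name = "score") {
    labels <- .checkScores(scores, labels)
    pts <- .rocPoints(scores, labels)
    auc <- .trapezoidAUC(pts$fpr, pts$tpr)
    higher <- TRUE
    if (auc < 0.5) {
        pts <- .rocPoints(-scores, labels)
        auc <- .trapezoidAUC(pts$fpr, pts$tpr)
        higher <- FALSE
    }
    new("ROCResult", name = name, fpr = pts$fpr, tpr = pts$tpr, auc = auc,
        ciLow = NA_real_, ciHigh = NA_real_, threshold = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        accuracy = NA_real_, higherIsPositive = higher)
}

#' DeLong 95 percent confidence interval for the AUC
#'
#' Nonparametric DeLong variance estimate, interval clipped to [0, 1].
#'
#' @param scores,labels as in [rocCurve()]; at least 5 subjects per class
#' @return c(ciLow, ciHigh)
#' @export
aucCI <- function(scores, labels) {
    labels <- .checkScores(scores, labels)
    if (min(table(labels)) < 5L)
        stop("need at least 5 subjects per class for a CI")
    r <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "auto", quiet = TRUE)
    ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
    c(ciLow = max(0, ci[1]), ciHigh = min(1, ci[3]))
}

#' Youden operating point
#'
#' The threshold maximizing sensitivity + specificity - 1 over all distinct
#' thresholds, ties broken toward higher specificity (then toward the more
#' conservative threshold). The decision rule is `score >= threshold` calls
#' high grade when `higherIsPositive`, `score <= threshold` otherwise.
#'
#' @param scores,labels as in [rocCurve()]
#' @param higherIsPositive orientation; NULL chooses automatically as
#'   [rocCurve()] does
#' @return list(threshold, rule, sensitivity, specificity, accuracy)
#' @export
youdenPoint <- function(scores, labels, higherIsPositive = NULL) {
    labels <- .checkScores(scores, labels)
    if (is.null(higherIsPositive))
        higherIsPositive <- rocCurve(scores, labels)@higherIsPositive
    s <- if (higherIsPositive) scores else -scores
    thr <- sort(unique(s), decreasing = TRUE)
    pos <- s[labels == 1L]; neg <- s[labels == 0L]
    best <- NULL
    for (t in thr) {
        sens <- mean(pos >= t)
        spec <- mean(neg < t)
        J <- sens + spec - 1
        if (is.null(best) || J > best$J + 1e-12 ||
            (abs(J - best$J) <= 1e-12 && spec > best$spec + 1e-12)) {
            best <- list(t = t, J = J, sens = sens, spec = spec)
        }
    }
    acc <- (sum(pos >= best$t) + sum(neg < best$t)) / length(s)
    list(threshold = if (higherIsPositive) best$t else -best$t,
         rule = if (higherIsPositive) ">=" else "<=",
         sensitivity = best$sens, specificity = best$spec, accuracy = acc)
}

#' Full ROC analysis of one score
#'
#' [rocCurve()] plus [aucCI()] plus [youdenPoint()] in one
#' [ROCResult-class].
#'
#' @inheritParams rocCurve
#' @param withCI compute the DeLong interval (needs >= 5 per class)
#' @return a [ROCResult-class] with all slots filled
#' @export
rocAnalysis <- function(scores, labels, name = "score", withCI = TRUE) {
    roc <- rocCurve(scores, labels, name)
    op <- youdenPoint(scores, labels, roc@higherIsPositive)
    roc@threshold <- op$threshold
    roc@sensitivity <- op$sensitivity
    roc@specificity <- op$specificity
    roc@accuracy <- op$accuracy
    if (withCI) {
        ci <- aucCI(scores, labels)
        roc@ciLow <- ci[["ciLow"]]
        roc@ciHigh <- ci[["ciHigh"]]
    }
    validObject(roc)
    roc
}

## Ridge-penalized logistic Newton iterations on standardized features
## (penalty on slopes only). Used as the separation fallback.
.ridgeLogistic <- function(X1, y, lambda = 1e-2, maxit = 200L) {
    p <- ncol(X1)
    pen <- diag(c(0, rep(lambda, p - 1L)), p)
    beta <- rep(0, p)
    for (i in seq_len(maxit)) {
        eta <- drop(X1 %*% beta)
        mu <- stats::plogis(eta)
        W <- mu * (1 - mu)
        g <- drop(crossprod(X1, y - mu)) - 2 * drop(pen %*% beta)
        H <- crossprod(X1, X1 * W) + 2 * pen
        step <- solve(H, g)
        beta <- beta + step
        if (max(abs(step)) < 1e-10) break
    }
    beta
}

#' Maximum-likelihood logistic classifier
#'
#' Features are standardized internally for numerical stability;
#' coefficients are reported on the original scale. Perfect separation or
#' ML non-convergence triggers a ridge-stabilized fallback fit, flagged via
#' `converged = FALSE` and `ridged = TRUE`, so a usable (finite) model is
#' always returned.
#'
#' @param features data.frame or matrix of per-subject feature values
#' @param labels logical or 0/1; TRUE/1 = positive (high-grade) class
#' @return a [LogisticModel-class]
#' @export
fitLogistic <- function(features, labels) {
    X <- as.matrix(features)
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    labels <- .checkScores(X[, 1], labels)
    if (any(!is.finite(X))) stop("missing values in features")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
        stop("constant feature: ", paste(colnames(X)[sds == 0],
                                         collapse = ", "))
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
        stop("collinear features (design matrix is rank-deficient)")
    ms <- colMeans(X)
    Xs <- sweep(sweep(X, 2, ms), 2, sds, "/")
    X1 <- cbind(`(Intercept)` = 1, Xs)

    separated <- FALSE
    fit <- withCallingHandlers(
        stats::glm.fit(X1, labels, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                      conditionMessage(w)))
                separated <<- TRUE
            invokeRestart("muffleWarning")
        })
    converged <- isTRUE(fit$converged) && !separated &&
        all(is.finite(fit$coefficients))
    if (converged) {
        bs <- fit$coefficients
        ridged <- FALSE
    } else {
        bs <- .ridgeLogistic(X1, labels)
        ridged <- TRUE
    }
    probs <- stats::plogis(drop(X1 %*% bs))
    probs <- .clamp(probs, 1e-12, 1 - 1e-12)
    ## back-transform to the original feature scale
    slopes <- bs[-1] / sds
    intercept <- bs[1] - sum(bs[-1] * ms / sds)
    coefs <- c(intercept, slopes)
    names(coefs) <- c("(Intercept)", colnames(X))
    new("LogisticModel", features = colnames(X), coefficients = coefs,
        converged = converged, ridged = ridged, probabilities = probs)
}

#' Combined multi-parameter diagnostic model
#'
#' Fits a multiple logistic regression of grade on the chosen parameters
#' (default: hindered diffusivity, restricted fraction and stretching
#' exponent) and evaluates its in-sample predicted probabilities with the
#' full ROC analysis — the combined-biomarker evaluation.
#'
#' @param cohort a [MADCohort-class]
#' @param features parameter columns to combine
#' @param withCI compute the DeLong interval
#' @return list(model = [LogisticModel-class], roc = [ROCResult-class])
#' @export
evaluateCombined <- function(cohort, features = c("Dh", "fr", "alphaH"),
                             withCI = TRUE) {
    tab <- cohortTable(cohort)
    if (!all(features %in% names(tab)))
        stop("features missing from cohort: ",
             paste(setdiff(features, names(tab)), collapse = ", "))
    labels <- tab$grade == "high"
    model <- fitLogistic(tab[, features, drop = FALSE], labels)
    roc <- rocAnalysis(model@probabilities, labels,
                       name = paste(features, collapse = "+"),
                       withCI = withCI)
    list(model = model, roc = roc)
}

#' Per-parameter and combined diagnostic table
#'
#' One full ROC analysis per listed parameter plus the combined logistic
#' model — sensitivity, specificity, accuracy, AUC and its 95 percent CI
#' per row.
#'
#' @param cohort a [MADCohort-class]
#' @param parameters single-parameter scores to evaluate
#' @param combined parameter set for the combined model (NULL to skip)
#' @return list(rocs = named list of [ROCResult-class], table = data.frame)
#' @export
diagnosticTable <- function(cohort,
                            parameters = c("ADC", "Dh", "fr", "alphaH"),
                            combined = c("Dh", "fr", "alphaH")) {
    tab <- cohortTable(cohort)
    labels <- tab$grade == "high"
    rocs <- lapply(parameters, function(nm)
        rocAnalysis(tab[[nm]], labels, name = nm))
    names(rocs) <- parameters
    if (!is.null(combined))
        rocs[[paste(combined, collapse = "+")]] <-
            evaluateCombined(cohort, combined)$roc
    out <- do.call(rbind, lapply(rocs, function(r)
        data.frame(name = r@name, sensitivity = r@sensitivity,
                   specificity = r@specificity, accuracy = r@accuracy,
                   auc = r@auc, ciLow = r@ciLow, ciHigh = r@ciHigh)))
    rownames(out) <- NULL
    list(rocs = rocs, table = out)
}
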