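test_that("empirical ROC handles separation, ties and orientation", {
    r1 <- rocCurve(c(1, 2, 3, 4), c(0, 0, 1, 1))
    expect_identical(aucValue(r1), 1)
    r2 <- rocCurve(c(1, 2, 3, 4), c(0, 1, 0, 1))
    expect_equal(aucValue(r2), 0.75)
    expect_equal(aucValue(r2),
                 concordanceAUCOracle(c(1, 2, 3, 4), c(0, 1, 0, 1)))
    ## flipping labels flips the orientation flag, not the AUC
    r3 <- rocCurve(c(1, 2, 3, 4), c(1, 1, 0, 0))
    expect_identical(aucValue(r3), 1)
    expect_false(r3@higherIsPositive)
    expect_true(r1@higherIsPositive)
    expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
    expect_error(rocCurve(1:4, c(0, 1)), "equal length")
})

test_that("trapezoid AUC equals pairwise concordance on exhaustive small cases", {
    set.seed(71)
    for (i in 1:30) {
        n <- sample(4:10, 1)
        labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
        ## integer scores force ties between and within classes
        scores <- sample(1:4, n, replace = TRUE)
        expect_equal(aucValue(rocCurve(scores, labels)),
                     concordanceAUCOracle(scores, labels),
                     tolerance = 1e-12)
    }
})

test_that("ROC points are invariant under strictly monotone score transforms", {
    set.seed(73)
    for (i in 1:5) {
        scores <- rnorm(30)
        labels <- rbinom(30, 1, 0.5)
        if (length(unique(labels)) < 2) next
        a <- rocCurve(scores, labels)
        b <- rocCurve(exp(2 * scores), labels)
        expect_equal(a@fpr, b@fpr)
        expect_equal(a@tpr, b@tpr)
        expect_equal(aucValue(a), aucValue(b))
    }
})

test_that("DeLong intervals clip, cover, and contain the point estimate", {
    sep <- aucCI(c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
                 c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1))
    expect_identical(unname(sep["ciHigh"]), 1)
    set.seed(79)
    for (i in 1:5) {
        scores <- rnorm(40) + rep(c(0, 0.8), each = 20)
        labels <- rep(c(0, 1), each = 20)
        ci <- aucCI(scores, labels)
        a <- aucValue(rocCurve(scores, labels))
        expect_true(ci["ciLow"] <= a && a <= ci["ciHigh"])
    }
    ## binormal coverage: theoretical AUC = Phi(delta/sqrt(2))
    delta <- 1
    theory <- pnorm(delta / sqrt(2))
    set.seed(83)
    covered <- 0
    for (i in 1:400) {
        scores <- c(rnorm(500), rnorm(500, mean = delta))
        labels <- rep(c(0, 1), each = 500)
        ci <- aucCI(scores, labels)
        if (ci["ciLow"] <= theory && theory <= ci["ciHigh"])
            covered <- covered + 1
    }
    ## nominal 95% interval: at least 93% empirical coverage
    expect_gte(covered, 372)
})

test_that("the Youden operating point matches an exhaustive threshold scan", {
    op <- youdenPoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
    expect_identical(op$sensitivity, 1)
    expect_identical(op$specificity, 1)
    expect_identical(op$accuracy, 1)

    ## brute-force scan oracle on a tied case
    scores <- c(1, 2, 3, 4); labels <- c(0, 1, 0, 1)
    bestJ <- -Inf; bestSpec <- -Inf
    for (t in sort(unique(scores), decreasing = TRUE)) {
        sens <- mean(scores[labels == 1] >= t)
        spec <- mean(scores[labels == 0] < t)
        J <- sens + spec - 1
        if (J > bestJ + 1e-12 ||
            (abs(J - bestJ) <= 1e-12 && spec > bestSpec)) {
            bestJ <- J; bestSpec <- spec; bestT <- t
        }
    }
    op2 <- youdenPoint(scores, labels)
    expect_identical(op2$threshold, bestT)
    expect_equal(op2$sensitivity + op2$specificity - 1, bestJ)

    ## self-consistency with a direct confusion matrix
    set.seed(89)
    s <- rnorm(40); l <- rbinom(40, 1, 0.5)
    op3 <- youdenPoint(s, l, higherIsPositive = TRUE)
    tp <- sum(s >= op3$threshold & l == 1)
    tn <- sum(s < op3$threshold & l == 0)
    expect_equal(op3$sensitivity, tp / sum(l == 1))
    expect_equal(op3$specificity, tn / sum(l == 0))
    expect_equal(op3$accuracy, (tp + tn) / 40)
})

test_that("logistic fits are sane on informative, null and degenerate designs", {
    set.seed(97)
    n <- 60
    x <- rnorm(n)
    labels <- rbinom(n, 1, plogis(2 * x))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    m <- fitLogistic(data.frame(x = x), labels)
    ## monotone transform: probability ROC equals raw-feature ROC
    expect_equal(aucValue(rocCurve(m@probabilities, labels)),
                 aucValue(rocCurve(x, labels)), tolerance = 1e-12)

    ## labels independent of features: near-chance AUC, small slopes
    set.seed(98)
    X <- data.frame(a = rnorm(200), b = rnorm(200))
    l0 <- rbinom(200, 1, 0.5)
    m0 <- fitLogistic(X, l0)
    expect_lt(abs(aucValue(rocCurve(m0@probabilities, l0)) - 0.5), 0.12)
    expect_true(all(abs(m0@coefficients[-1]) < 1))

    expect_error(fitLogistic(data.frame(a = rep(1, 10)),
                             rep(c(0, 1), 5)), "constant feature")
    dup <- data.frame(a = rnorm(10))
    dup$b <- dup$a
    expect_error(fitLogistic(dup, rep(c(0, 1), 5)), "collinear")

    ## perfect separation falls back to a flagged ridge fit
    xs <- c(rnorm(10, -3), rnorm(10, 3))
    ls <- rep(c(0, 1), each = 10)
    ms <- fitLogistic(data.frame(x = xs), ls)
    expect_false(ms@converged)
    expect_true(ms@ridged)
    expect_true(all(is.finite(ms@coefficients)))
    expect_true(all(ms@probabilities > 0 & ms@probabilities < 1))
})

test_that("combined models evaluate deterministically and separate when a feature does", {
    ## zero-variance groups: one feature fully separates the grades
    d0l <- gradeDistribution("low", .zeroSdMeans(), .zeroSds())
    mh <- .zeroSdMeans(); mh["Dh"] <- 1.254
    d0h <- gradeDistribution("high", mh, .zeroSds())
    c0 <- makeCohort(6, 6, d0l, d0h, seed = 2L)
    tab0 <- cohortTable(c0)
    expect_identical(aucValue(rocCurve(tab0$Dh, tab0$grade == "high")), 1)
    comb0 <- evaluateCombined(c0, features = "Dh", withCI = FALSE)
    expect_identical(aucValue(comb0$roc), 1)

    co <- makeCohort(20, 20, seed = 5L)
    e1 <- evaluateCombined(co, withCI = FALSE)
    e2 <- evaluateCombined(co, withCI = FALSE)
    expect_identical(e1$roc@auc, e2$roc@auc)
    expect_identical(e1$model@coefficients, e2$model@coefficients)
    expect_error(evaluateCombined(co, features = c("Dh", "nope")),
                 "missing from cohort")
})

test_that("the diagnostic table covers every score plus the combined model", {
    co <- makeCohort(15, 15, seed = 9L)
    d <- diagnosticTable(co)
    expect_identical(nrow(d$table), 5L)
    expect_true("Dh+fr+alphaH" %in% d$table$name)
    expect_true(all(d$table$auc >= 0.5 & d$table$auc <= 1))
    expect_true(all(d$table$ciLow <= d$table$auc &
                    d$table$auc <= d$table$ciHigh))
})
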