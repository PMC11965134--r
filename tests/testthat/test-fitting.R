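test_that("ADC log-linear fit matches the closed-form OLS slope", {
    sch2 <- bValueScheme(c(0, 1000))
    two <- signalCurve(c(1, exp(-1)), sch2)
    fit <- fitADC(two)
    expect_equal(fit@adc, 1, tolerance = 1e-12)
    expect_equal(fit@rSquared, 1, tolerance = 1e-12)
    expect_identical(fit@nPointsUsed, 2L)

    flat <- signalCurve(rep(1, 12), defaultScheme())
    expect_equal(fitADC(flat)@adc, 0, tolerance = 1e-14)

    ## oracle equivalence on random smooth curves
    set.seed(21)
    sch <- defaultScheme()
    for (i in 1:8) {
        p <- randomIdentifiableParams()
        y <- signalValues(madSignalCurve(p, sch))
        o <- olsLogSlopeOracle(bValues(sch), y)
        f <- fitADC(signalCurve(y, sch))
        expect_equal(f@adc, -unname(o["slope"]), tolerance = 1e-12)
        expect_equal(f@intercept, unname(o["intercept"]), tolerance = 1e-12)
    }
})

test_that("ADC fit drops sub-floor signals and errors on degenerate input", {
    sch <- bValueScheme(c(0, 500, 1000, 3000))
    y <- c(1, exp(-0.5), exp(-1), 1e-9)
    fit <- fitADC(signalCurve(y, sch), fitConfig(minSignalFloor = 1e-6))
    expect_identical(fit@nPointsUsed, 3L)
    expect_equal(fit@adc, 1, tolerance = 1e-10)
    expect_error(fitADC(signalCurve(c(1, 1e-9, 1e-9, 1e-9), sch)),
                 "degenerate")
})

test_that("segmented initialization lands in the right regime", {
    sch <- defaultScheme()
    mono <- signalCurve(monoSignal(1, bValues(sch)), sch)
    init <- initializeMAD(mono)
    pv <- paramVector(init)
    expect_gt(pv["fh"], max(pv["fr"], pv["fui"], pv["ff"]))
    expect_gte(pv["Dh"], 0.5)
    expect_lte(pv["Dh"], 1.5)

    flat <- signalCurve(rep(1, 12), sch)
    pvf <- paramVector(initializeMAD(flat))
    expect_gt(pvf["fr"], max(pvf["fh"], pvf["fui"], pvf["ff"]))

    ## initialization always yields a valid parameter set
    set.seed(33)
    for (i in 1:10) {
        y <- signalValues(madSignalCurve(randomIdentifiableParams(), sch))
        expect_true(validObject(initializeMAD(signalCurve(y, sch))))
    }
    noHighB <- bValueScheme(c(0, 50, 100, 500, 1000, 1800))
    expect_error(initializeMAD(signalCurve(exp(-bValues(noHighB)),
                                           noHighB)),
                 "high-b")
    noLowB <- bValueScheme(c(0, 500, 1000, 1500, 2500))
    expect_error(initializeMAD(signalCurve(exp(-bValues(noLowB)),
                                           noLowB)),
                 "low-b")
})

test_that("noiseless MAD fits recover the generating parameters", {
    sch <- defaultScheme()
    ## nested mono-exponential truth
    mono <- signalCurve(monoSignal(1, bValues(sch)), sch)
    fit <- fitMAD(mono)
    pv <- paramVector(madParams(fit))
    expect_gte(pv[["fh"]], 0.99)
    expect_equal(pv[["Dh"]], 1, tolerance = 0.01)
    expect_equal(pv[["alphaH"]], 1, tolerance = 0.02)

    ## a random interior truth is recovered to near machine precision
    set.seed(7)
    truth <- randomIdentifiableParams()
    fit2 <- fitMAD(madSignalCurve(truth, sch))
    expect_lt(fit2@residualNorm, 1e-8)
    tv <- paramVector(truth); fv <- paramVector(madParams(fit2))
    expect_equal(unname(fv[c("Dh", "Df", "alphaH")]),
                 unname(tv[c("Dh", "Df", "alphaH")]), tolerance = 1e-4)
    expect_equal(unname(fv[c("fr", "fh", "fui", "ff")]),
                 unname(tv[c("fr", "fh", "fui", "ff")]), tolerance = 1e-4)
})

test_that("fitted fractions always sum to one inside bounds", {
    sch <- defaultScheme()
    set.seed(55)
    for (i in 1:5) {
        y <- signalValues(madSignalCurve(randomIdentifiableParams(), sch))
        fv <- paramVector(madParams(fitMAD(signalCurve(y, sch))))
        expect_equal(sum(fv[c("fr", "fh", "fui", "ff")]), 1,
                     tolerance = 1e-9)
        expect_true(all(fv[c("fr", "fh", "fui", "ff")] >= 0))
        expect_true(fv["Dh"] >= 0.2 && fv["Dh"] <= 3)
        expect_true(fv["alphaH"] > 0 && fv["alphaH"] <= 2)
    }
})

test_that("flat and invalid curves are handled at the boundary", {
    sch <- defaultScheme()
    flat <- signalCurve(rep(1, 12), sch)
    fit <- fitMAD(flat)
    expect_true(fit@converged)
    ## essentially no decay over the whole range
    expect_gt(madSignal(madParams(fit), 3), 0.97)
    expect_true(any(fit@atBoundFlags))

    raw <- signalCurve(c(2, rep(1, 11)), sch)
    expect_error(fitMAD(raw), "normalized")
    few <- bValueScheme(c(0, 200, 500, 1000, 2500))
    expect_error(fitMAD(signalCurve(exp(-bValues(few)), few)),
                 "6 distinct")
})

test_that("fits are deterministic for a fixed configuration", {
    sch <- defaultScheme()
    set.seed(9)
    y <- signalValues(madSignalCurve(randomIdentifiableParams(), sch))
    cfg <- fitConfig(seed = 42L)
    f1 <- fitMAD(signalCurve(y, sch), cfg)
    f2 <- fitMAD(signalCurve(y, sch), cfg)
    expect_identical(paramVector(madParams(f1)), paramVector(madParams(f2)))
    expect_identical(f1@residualNorm, f2@residualNorm)
})

test_that("volume fitting is voxel-wise consistent and mask-aware", {
    sch <- defaultScheme()
    truth <- lowGradeParams()
    y <- signalValues(madSignalCurve(truth, sch))
    dwi <- array(rep(y, each = 4), dim = c(2, 2, 1, 12))
    mask <- array(TRUE, dim = c(2, 2, 1))
    mask[2, 2, 1] <- FALSE
    cfg <- fitConfig()
    maps <- fitVolume(dwi, sch, mask, cfg)
    single <- fitMAD(signalCurve(y, sch), cfg)
    sv <- paramVector(madParams(single))
    for (nm in c("Dr", "Dh", "Df", "fr", "fh", "fui", "ff", "alphaH")) {
        m <- paramMap(maps, nm)
        expect_identical(m[1, 1, 1], unname(sv[nm]))
        expect_identical(m[2, 1, 1], m[1, 2, 1])
        expect_true(is.nan(m[2, 2, 1]))
    }
    expect_equal(paramMap(maps, "ADC")[1, 1, 1],
                 fitADC(signalCurve(y, sch), cfg)@adc, tolerance = 1e-14)

    ## bit-identical on re-run
    maps2 <- fitVolume(dwi, sch, mask, cfg)
    expect_identical(maps@maps, maps2@maps)

    expect_error(fitVolume(dwi, sch, array(TRUE, dim = c(3, 2, 1)), cfg),
                 "mask shape")
    expect_error(fitVolume(dwi, sch, array(FALSE, dim = c(2, 2, 1)), cfg),
                 "empty mask")
    expect_error(fitVolume(dwi, bValueScheme(c(0, 1000)), mask, cfg),
                 "does not match scheme")
})
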