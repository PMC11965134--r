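test_that("the default acquisition scheme matches the reference protocol", {
    sch <- defaultScheme()
    expect_identical(length(bValues(sch)), 12L)
    expect_equal(bValues(sch),
                 c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 0.8, 1.0, 1.5, 2.0,
                   2.5, 3.0), tolerance = 1e-12)
    expect_identical(nAverages(sch),
                     c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 3L, 4L, 6L, 8L, 9L))
    expect_true(validObject(sch))
})

test_that("Rician noise has the Rayleigh mean on zero signal and averages down", {
    ## many b-entries used purely as independent replicate slots
    n <- 50000L
    sch <- bValueScheme(seq(0, by = 1, length.out = n), units = "ms/um2")
    zeros <- new("SignalCurve", scheme = sch, values = rep(0, n),
                 normalized = FALSE)
    sigma <- 0.37
    noisy <- addRicianNoise(zeros, noiseConfig(sigma, applyAveraging = FALSE,
                                               seed = 5L))
    expect_equal(mean(signalValues(noisy)), sigma * sqrt(pi / 2),
                 tolerance = 0.01)

    ## NEX = 4 cuts the variance of the averaged magnitude ~4-fold
    sch4 <- new("BValueScheme", bValues = seq(0, by = 1, length.out = n),
                nAverages = rep(4L, n))
    ones <- new("SignalCurve", scheme = sch, values = rep(1, n),
                normalized = FALSE)
    ones4 <- new("SignalCurve", scheme = sch4, values = rep(1, n),
                 normalized = FALSE)
    v1 <- var(signalValues(addRicianNoise(ones, noiseConfig(0.1, seed = 6L))))
    v4 <- var(signalValues(addRicianNoise(ones4, noiseConfig(0.1, seed = 7L))))
    expect_equal(v4 / v1, 0.25, tolerance = 0.06)

    ## sigma = 0 is the identity; fixed seed reproduces bit-exactly
    expect_identical(signalValues(addRicianNoise(zeros, noiseConfig(0))),
                     signalValues(zeros))
    a <- addRicianNoise(ones, noiseConfig(0.2, seed = 9L))
    b <- addRicianNoise(ones, noiseConfig(0.2, seed = 9L))
    expect_identical(signalValues(a), signalValues(b))
})

test_that("subject draws honor the generating distribution", {
    ## zero SDs return the renormalized means exactly
    d0 <- gradeDistribution("low", .zeroSdMeans(), .zeroSds())
    p0 <- sampleSubjectParams(d0, seed = 3L)
    expect_equal(paramVector(p0), paramVector(lowGradeParams()),
                 tolerance = 1e-12)

    ## draws always satisfy the parameter invariants
    dl <- lowGradeDistribution()
    for (s in 1:200)
        expect_true(validObject(sampleSubjectParams(dl, seed = s)))

    ## hindered-diffusivity draws center on the group mean (truncation
    ## negligible at these moments)
    dh <- vapply(1:3000, function(s)
        paramVector(sampleSubjectParams(dl, seed = s))[["Dh"]], numeric(1))
    expect_equal(mean(dh), 1.360, tolerance = 0.02)
})

test_that("noiseless phantoms carry exact forward-model voxels and truth", {
    u <- uniformFittedPhantom()
    ph <- u$phantom
    y <- signalValues(madSignalCurve(lowGradeParams(), ph$scheme))
    for (v in 1:3)
        expect_equal(unname(ph$dwi[v, 1, 1, ]), unname(y),
                     tolerance = 1e-12)
    expect_true(all(is.finite(ph$truth@truthMaps[["Dh"]][ph$truth@labels != 0])))
    expect_true(all(ph$truth@labels == 1L))

    ## phantom generation is reproducible and rejects overlapping lesions
    shape <- c(4, 2, 1)
    les <- list(low = phantomLesionBox(shape, c(1, 1, 1), c(2, 2, 1)),
                high = phantomLesionBox(shape, c(3, 1, 1), c(4, 2, 1)))
    p1 <- makePhantom(shape, les, noise = noiseConfig(0.02, seed = 2L),
                      seed = 8L)
    p2 <- makePhantom(shape, les, noise = noiseConfig(0.02, seed = 2L),
                      seed = 8L)
    expect_identical(p1$dwi, p2$dwi)
    bad <- list(low = phantomLesionBox(shape, c(1, 1, 1), c(3, 2, 1)),
                high = phantomLesionBox(shape, c(3, 1, 1), c(4, 2, 1)))
    expect_error(makePhantom(shape, bad), "disjoint")
})

test_that("phantom fitting recovers truth in the vanishing-noise limit", {
    dist0 <- gradeDistribution("low", .zeroSdMeans(), .zeroSds())
    shape <- c(2, 2, 1)
    les <- list(low = array(TRUE, dim = shape))
    ph <- makePhantom(shape, les, dists = list(low = dist0),
                      noise = noiseConfig(1e-6, seed = 4L), seed = 1L)
    maps <- fitVolume(ph$dwi, ph$scheme, array(TRUE, dim = shape))
    tv <- paramVector(lowGradeParams())
    for (nm in c("Dh", "Df", "alphaH"))
        expect_equal(median(paramMap(maps, nm)), unname(tv[nm]),
                     tolerance = 0.02)
    for (nm in c("fr", "fh", "fui", "ff"))
        expect_lt(abs(median(paramMap(maps, nm)) - tv[nm]), 0.02)
})

test_that("synthetic cohorts have the declared composition and converge in mean", {
    co <- makeCohort(30, 24, seed = 17L)
    tab <- cohortTable(co)
    expect_identical(nrow(tab), 54L)
    expect_identical(sum(tab$grade == "low"), 30L)
    expect_identical(sum(tab$grade == "high"), 24L)
    expect_false(anyDuplicated(tab$subject) > 0)
    expect_identical(provenance(co)$seed, 17L)
    expect_identical(cohortTable(makeCohort(30, 24, seed = 17L)), tab)

    ## zero-SD cohort: all low-grade records identical
    d0l <- gradeDistribution("low", .zeroSdMeans(), .zeroSds())
    mh <- .zeroSdMeans(); mh["Dh"] <- 1.254
    d0h <- gradeDistribution("high", mh, .zeroSds())
    c0 <- cohortTable(makeCohort(4, 4, d0l, d0h, seed = 1L))
    low0 <- c0[c0$grade == "low", setdiff(names(c0), c("subject", "nVoxels"))]
    expect_true(all(vapply(low0, function(col)
        length(unique(col)) == 1L, logical(1))))

    ## law of large numbers on an un-renormalized quantity
    big <- cohortTable(makeCohort(4000, 2, seed = 23L))
    dh <- big$Dh[big$grade == "low"]
    expect_lt(abs(mean(dh) - 1.360), 3 * 0.112 / sqrt(4000))
})
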