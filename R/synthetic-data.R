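#' @include AllClasses.R model-core.R fitting.R
NULL

#' The reference 12-b-value acquisition scheme
#'
#' b = 0, 20, 50, 100, 200, 500, 800, 1000, 1500, 2000, 2500, 3000 s/mm^2
#' with per-b averaging counts (NEX) 1, 1, 1, 1, 1, 2, 3, 3, 4, 6, 8, 9:
#' the dense low-b sampling resolves the fast flow compartment, the heavy
#' high-b averaging offsets the low SNR where restricted diffusion
#' dominates. Returned in the internal ms/um^2 unit.
#'
#' @return a [BValueScheme-class]
#' @export
defaultScheme <- function() {
    bValueScheme(c(0, 20, 50, 100, 200, 500, 800, 1000, 1500, 2000,
                   2500, 3000),
                 c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 3L, 4L, 6L, 8L, 9L),
                 units = "s/mm2")
}

## Reference ROI-level distributions for the two nuclear-grade groups of
## clear cell renal cell carcinoma (means and SDs of the eight MAD
## quantities plus ADC). For quantities reported as median (IQR) the SD is
## approximated as IQR/1.349, the normal-theory conversion.
.lowGradeMeans <- c(Dr = 0.039, Dh = 1.360, Df = 15.012, fr = 0.060,
                    fh = 0.413, fui = 0.275, ff = 0.219, alphaH = 0.872,
                    ADC = 0.924)
.lowGradeSds <- c(Dr = (0.072 - 0.014) / 1.349, Dh = 0.112, Df = 1.8,
                  fr = 0.005, fh = 0.029, fui = (0.373 - 0.224) / 1.349,
                  ff = 0.023, alphaH = 0.224, ADC = 0.081)
.highGradeMeans <- c(Dr = 0.045, Dh = 1.254, Df = 14.335, fr = 0.080,
                     fh = 0.442, fui = 0.274, ff = 0.196, alphaH = 0.896,
                     ADC = 0.854)
.highGradeSds <- c(Dr = (0.069 - 0.033) / 1.349, Dh = 0.134, Df = 1.2,
                   fr = 0.009, fh = 0.031, fui = (0.320 - 0.230) / 1.349,
                   ff = 0.022, alphaH = 0.393, ADC = 0.045)

## Truncation bounds applied to every draw (the physical parameter ranges).
.truncLower <- c(Dr = 0, Dh = 0.2, Df = 3 + 1e-6, fr = 0, fh = 0, fui = 0,
                 ff = 0, alphaH = 1e-3, ADC = 0)
.truncUpper <- c(Dr = 0.2 - 1e-6, Dh = 3, Df = 100, fr = 1, fh = 1,
                 fui = 1, ff = 1, alphaH = 2, ADC = 4)

#' Per-grade generating distributions
#'
#' Reference ROI-mean distributions for low-grade (WHO-ISUP 1-2) and
#' high-grade (WHO-ISUP 3-4) clear cell renal cell carcinoma. `gradeDistribution()`
#' builds a custom one.
#'
#' @param grade "low" or "high"
#' @param means,sds named numeric vectors over Dr, Dh, Df, fr, fh, fui, ff,
#'   alphaH, ADC
#' @return a [GradeParameterDistribution-class]
#' @export
gradeDistribution <- function(grade, means, sds) {
    new("GradeParameterDistribution", grade = grade,
        means = means[.COHORT_PARAM_NAMES], sds = sds[.COHORT_PARAM_NAMES])
}

#' @rdname gradeDistribution
#' @export
lowGradeDistribution <- function() {
    gradeDistribution("low", .lowGradeMeans, .lowGradeSds)
}

#' @rdname gradeDistribution
#' @export
highGradeDistribution <- function() {
    gradeDistribution("high", .highGradeMeans, .highGradeSds)
}

#' Rician noise configuration
#'
#' @param sigma per-channel Gaussian noise scale relative to S(0); an SNR
#'   of 50 at b = 0 corresponds to `sigma = 1/50`
#' @param applyAveraging average nAverages independent magnitude draws per
#'   b-value, as a scanner's NEX averaging does
#' @param gaussian additive Gaussian noise instead of Rician (debug mode)
#' @param seed integer seed
#' @return a [NoiseConfig-class]
#' @export
noiseConfig <- function(sigma, applyAveraging = TRUE, gaussian = FALSE,
                        seed = 1L) {
    new("NoiseConfig", sigma = sigma, applyAveraging = applyAveraging,
        gaussian = gaussian, seed = as.integer(seed))
}

## One Rician (or Gaussian) corruption of a clean value vector: the mean of
## `nav` independent magnitude draws |x + n1 + i n2|.
.noisyValues <- function(clean, sigma, nav, gaussian) {
    out <- numeric(length(clean))
    for (j in seq_along(clean)) {
        if (gaussian) {
            out[j] <- mean(clean[j] + stats::rnorm(nav[j], sd = sigma))
        } else {
            re <- clean[j] + stats::rnorm(nav[j], sd = sigma)
            im <- stats::rnorm(nav[j], sd = sigma)
            out[j] <- mean(sqrt(re^2 + im^2))
        }
    }
    out
}

#' Corrupt a signal curve with magnitude (Rician) noise
#'
#' Each b-value receives the mean of `nAverages` independent magnitude
#' draws |S + n1 + i n2| with per-channel Gaussian noise of scale `sigma`,
#' mirroring scanner NEX averaging. With `applyAveraging = FALSE` a single
#' draw is used everywhere. Deterministic for a fixed seed.
#'
#' @param clean a [SignalCurve-class]
#' @param noise a [NoiseConfig-class]
#' @return a [SignalCurve-class]; `sigma = 0` returns the input unchanged
#' @export
addRicianNoise <- function(clean, noise) {
    stopifnot(is(clean, "SignalCurve"), is(noise, "NoiseConfig"))
    if (noise@sigma == 0) return(clean)
    nav <- if (noise@applyAveraging) clean@scheme@nAverages
           else rep(1L, length(clean@values))
    vals <- .withSeed(noise@seed,
        .noisyValues(clean@values, noise@sigma, nav, noise@gaussian))
    new("SignalCurve", scheme = clean@scheme, values = vals,
        normalized = FALSE)
}

## Truncated-normal scalar draw by rejection; falls back to clamping after
## many misses (cannot happen for means inside the bounds).
.rtruncnorm1 <- function(mean, sd, lo, hi) {
    if (sd == 0) return(.clamp(mean, lo, hi))
    for (i in 1:1000) {
        x <- stats::rnorm(1, mean, sd)
        if (x >= lo && x <= hi) return(x)
    }
    .clamp(mean, lo, hi)
}

## Draw the full nine-quantity parameter vector (fractions renormalized to
## unit sum). Runs inside an existing RNG stream.
.drawParamVector <- function(dist) {
    x <- vapply(.COHORT_PARAM_NAMES, function(nm)
        .rtruncnorm1(dist@means[nm], dist@sds[nm],
                     .truncLower[nm], .truncUpper[nm]), numeric(1))
    fr4 <- c("fr", "fh", "fui", "ff")
    x[fr4] <- x[fr4] / sum(x[fr4])
    x
}

#' Draw one subject's ROI-mean MAD parameters
#'
#' Independent truncated-normal draws per quantity from the grade's
#' distribution; fractions renormalized to unit sum. With all SDs zero the
#' (renormalized) means are returned exactly.
#'
#' @param dist a [GradeParameterDistribution-class]
#' @param seed integer seed
#' @return a valid [MADParameters-class]
#' @export
sampleSubjectParams <- function(dist, seed = 1L) {
    x <- .withSeed(seed, .drawParamVector(dist))
    madParameters(Dr = x["Dr"], Dh = x["Dh"], Df = x["Df"], fr = x["fr"],
                  fh = x["fh"], fui = x["fui"], ff = x["ff"],
                  alphaH = x["alphaH"])
}

#' Mark a rectangular lesion in a volume
#'
#' @param shape spatial dimensions c(nx, ny, nz)
#' @param from,to inclusive 1-based corner indices
#' @return a 3D logical array
#' @export
phantomLesionBox <- function(shape, from, to) {
    m <- array(FALSE, dim = shape)
    m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
    m
}

#' Build a synthetic multi-b DWI phantom with known truth
#'
#' Every voxel of a lesion draws its own MAD parameter set from that
#' lesion's grade distribution; its clean curve is the MAD forward model
#' scaled by `s0`. Background voxels contain pure noise. Rician noise with
#' NEX averaging (per `noise`) corrupts the whole 4D volume. The generating
#' parameter values are returned voxel-by-voxel as ground truth (the truth
#' ADC is the log-linear slope of the clean curve).
#'
#' @param shape spatial dimensions c(nx, ny, nz)
#' @param lesions named list of 3D logical arrays; names are grades
#'   ("low"/"high") or names of entries in `dists`. Regions must be
#'   disjoint and inside `shape`.
#' @param dists named list of [GradeParameterDistribution-class] keyed by
#'   the lesion names (defaults to the reference low/high distributions)
#' @param scheme a [BValueScheme-class]
#' @param noise a [NoiseConfig-class]
#' @param s0 unweighted signal amplitude
#' @param seed integer seed for the parameter draws (noise uses its own)
#' @return list(dwi = 4D array, truth = [PhantomTruth-class],
#'   scheme = scheme)
#' @export
makePhantom <- function(shape, lesions,
                        dists = list(low = lowGradeDistribution(),
                                     high = highGradeDistribution()),
                        scheme = defaultScheme(),
                        noise = noiseConfig(0, seed = 1L),
                        s0 = 1, seed = 1L) {
    stopifnot(length(shape) == 3L, length(lesions) >= 1L)
    overlap <- Reduce(`+`, lapply(lesions, function(m) array(as.integer(m),
                                                             dim = shape)))
    if (any(overlap > 1L)) stop("lesion regions must be disjoint")
    nb <- length(scheme@bValues)
    dwi <- array(0, dim = c(shape, nb))
    labels <- array(0L, dim = shape)
    truthMaps <- lapply(c(.MAD_PARAM_NAMES, "ADC"), function(nm)
        array(.SENTINEL, dim = shape))
    names(truthMaps) <- c(.MAD_PARAM_NAMES, "ADC")
    bv <- scheme@bValues
    mb <- mean(bv); sxx <- sum((bv - mb)^2)

    .withSeed(seed, {
        for (li in seq_along(lesions)) {
            nm <- names(lesions)[li]
            dist <- dists[[nm]]
            if (is.null(dist))
                stop("no distribution supplied for lesion '", nm, "'")
            idx <- which(lesions[[li]])
            coords <- arrayInd(idx, shape)
            lab <- if (identical(dist@grade, "low")) 1L else 2L
            for (i in seq_along(idx)) {
                x <- .drawParamVector(dist)
                p <- madParameters(Dr = x["Dr"], Dh = x["Dh"],
                                   Df = x["Df"], fr = x["fr"],
                                   fh = x["fh"], fui = x["fui"],
                                   ff = x["ff"], alphaH = x["alphaH"])
                clean <- madSignal(p, bv)
                dwi[coords[i, 1], coords[i, 2], coords[i, 3], ] <-
                    s0 * clean
                pv <- paramVector(p)
                for (q in .MAD_PARAM_NAMES)
                    truthMaps[[q]][idx[i]] <- pv[q]
                ly <- log(clean)
                truthMaps[["ADC"]][idx[i]] <-
                    -sum((bv - mb) * (ly - mean(ly))) / sxx
                labels[idx[i]] <- lab
            }
        }
    })
    if (noise@sigma > 0) {
        sig <- noise@sigma * s0
        nav <- if (noise@applyAveraging) scheme@nAverages
               else rep(1L, nb)
        dwi <- .withSeed(noise@seed, {
            out <- dwi
            for (j in seq_len(nb)) {
                acc <- 0
                for (k in seq_len(nav[j])) {
                    if (noise@gaussian) {
                        acc <- acc + out[, , , j, drop = FALSE] +
                            array(stats::rnorm(prod(shape), sd = sig), dim = c(shape, 1))
                    } else {
                        re <- out[, , , j, drop = FALSE] +
                            array(stats::rnorm(prod(shape), sd = sig), dim = c(shape, 1))
                        im <- array(stats::rnorm(prod(shape), sd = sig), dim = c(shape, 1))
                        acc <- acc + sqrt(re^2 + im^2)
                    }
                }
                out[, , , j] <- acc / nav[j]
            }
            out
        })
    }
    truth <- new("PhantomTruth", truthMaps = truthMaps, labels = labels)
    list(dwi = dwi, truth = truth, scheme = scheme)
}

#' Simulate a two-group subject cohort
#'
#' One draw per subject of the full nine-quantity ROI-mean vector from the
#' subject's grade distribution (a subject-level draw stands in for ROI
#' averaging over many voxels). Deterministic for a fixed seed.
#'
#' @param nLow,nHigh group sizes (each >= 2); the reference study design is
#'   30 low-grade and 24 high-grade subjects
#' @param lowDist,highDist [GradeParameterDistribution-class] objects
#' @param seed integer seed
#' @return a [MADCohort-class]
#' @export
makeCohort <- function(nLow = 30L, nHigh = 24L,
                       lowDist = lowGradeDistribution(),
                       highDist = highGradeDistribution(), seed = 1L) {
    stopifnot(nLow >= 2L, nHigh >= 2L)
    n <- nLow + nHigh
    grades <- c(rep("low", nLow), rep("high", nHigh))
    rows <- .withSeed(seed, {
        nvox <- sample(50:500, n, replace = TRUE)
        lapply(seq_len(n), function(i) {
            d <- if (grades[i] == "low") lowDist else highDist
            x <- .drawParamVector(d)
            c(x, nVoxels = nvox[i])
        })
    })
    tab <- as.data.frame(do.call(rbind, rows))
    tab <- cbind(subject = sprintf("S%03d", seq_len(n)), grade = grades,
                 tab, stringsAsFactors = FALSE)
    tab$nVoxels <- as.integer(tab$nVoxels)
    new("MADCohort", table = tab,
        provenance = list(source = "synthetic", seed = as.integer(seed)))
}
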