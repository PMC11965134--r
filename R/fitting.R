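#' @include AllClasses.R model-core.R
#' @importFrom minpack.lm nls.lm nls.lm.control
NULL

.FREE_PARAMS <- c("Dr", "Dh", "Df", "alphaH", "fr", "fh", "fui")

## Default box constraints for the free parameters. Dr's upper edge sits just
## inside the open bound; Df's lower edge just above the unimpeded constant.
.defaultLower <- c(Dr = 0, Dh = 0.2, Df = 3 + 1e-6, alphaH = 1e-3,
                   fr = 0, fh = 0, fui = 0)
.defaultUpper <- c(Dr = 0.2 - 1e-6, Dh = 3, Df = 100, alphaH = 2,
                   fr = 1, fh = 1, fui = 1)

#' Build an optimizer configuration
#'
#' @param lower,upper named bounds over Dr, Dh, Df, alphaH, fr, fh, fui;
#'   defaults reproduce the model's physical ranges
#' @param nMultistart optimizer starts; the first is the segmented
#'   log-linear heuristic, the others seeded perturbations of it. Four-term
#'   exponential least squares has local minima, so keep this > 1.
#' @param maxIterations,residualTolerance,relStepTolerance
#'   Levenberg-Marquardt controls
#' @param seed seed for start-point jitter (fit results are deterministic
#'   for a fixed config)
#' @param minSignalFloor signals at or below this level are dropped from
#'   log-linear fits rather than clamped
#' @return a [FitConfig-class]
#' @export
fitConfig <- function(lower = .defaultLower, upper = .defaultUpper,
                      nMultistart = 8L, maxIterations = 200L,
                      residualTolerance = 1e-12, relStepTolerance = 1e-12,
                      seed = 20251L, minSignalFloor = 1e-6) {
    new("FitConfig", lower = lower[.FREE_PARAMS], upper = upper[.FREE_PARAMS],
        nMultistart = as.integer(nMultistart),
        maxIterations = as.integer(maxIterations),
        residualTolerance = residualTolerance,
        relStepTolerance = relStepTolerance, seed = as.integer(seed),
        minSignalFloor = minSignalFloor)
}

#' Mono-exponential ADC by log-linear least squares
#'
#' Ordinary least squares of log signal on b over all b-values, the
#' conventional ADC definition for a fixed multi-b protocol. Signals at or
#' below the floor are excluded (with the used count recorded), never
#' clamped. A negative slope estimate yields `physical = FALSE`.
#'
#' @param curve a [SignalCurve-class]
#' @param config a [FitConfig-class]
#' @return an [ADCFit-class]
#' @export
fitADC <- function(curve, config = fitConfig()) {
    stopifnot(is(curve, "SignalCurve"))
    b <- curve@scheme@bValues
    y <- curve@values
    use <- is.finite(y) & y > config@minSignalFloor
    if (sum(use) < 2L)
        stop("degenerate input: fewer than 2 points above the signal floor")
    b <- b[use]; ly <- log(y[use])
    mb <- mean(b); ml <- mean(ly)
    sxx <- sum((b - mb)^2)
    slope <- sum((b - mb) * (ly - ml)) / sxx
    intercept <- ml - slope * mb
    ssres <- sum((ly - (intercept + slope * b))^2)
    sstot <- sum((ly - ml)^2)
    r2 <- if (sstot < 1e-300) {
        if (ssres < 1e-300) 1 else 0
    } else .clamp(1 - ssres / sstot, 0, 1)
    adc <- -slope
    new("ADCFit", adc = adc, intercept = intercept, rSquared = r2,
        nPointsUsed = as.integer(sum(use)), physical = adc >= 0)
}

## Log-slope of a curve over the points selected by `keep`; NA when fewer
## than two usable points.
.segmentSlope <- function(b, y, keep, floor) {
    keep <- keep & is.finite(y) & y > floor
    if (sum(keep) < 2L) return(NA_real_)
    b <- b[keep]; ly <- log(y[keep])
    sum((b - mean(b)) * (ly - mean(ly))) / sum((b - mean(b))^2)
}

#' Segmented log-linear start point for the MAD fit
#'
#' A deterministic heuristic: the flow compartment dominates the initial
#' drop (b <= 0.1 ms/um^2), the hindered compartment the mid range
#' (0.2 <= b <= 1.0), and the restricted fraction the high-b plateau
#' (b >= 2.0). Fractions are clipped and renormalized so the start always
#' satisfies the model invariants.
#'
#' @param curve a normalized [SignalCurve-class] whose scheme has at least
#'   two points at b <= 0.1 and one at b >= 2.0 ms/um^2
#' @param config a [FitConfig-class] (bounds used for clipping)
#' @return a valid [MADParameters-class] start point
#' @export
initializeMAD <- function(curve, config = fitConfig()) {
    stopifnot(is(curve, "SignalCurve"))
    b <- curve@scheme@bValues
    y <- curve@values
    if (sum(b <= 0.1) < 2L)
        stop("initialization error: scheme lacks low-b (<= 0.1 ms/um^2) points")
    if (!any(b >= 2.0))
        stop("initialization error: scheme lacks high-b (>= 2.0 ms/um^2) points")
    lo <- config@lower; hi <- config@upper

    sLow <- .segmentSlope(b, y, b <= 0.1, config@minSignalFloor)
    sMid <- .segmentSlope(b, y, b >= 0.2 & b <= 1.0, config@minSignalFloor)
    if (is.na(sMid)) sMid <- if (is.na(sLow)) 0 else sLow

    Dh0 <- .clamp(-sMid, lo["Dh"], hi["Dh"])
    ## plateau at high b approximates the restricted fraction (other
    ## compartments have decayed there)
    plateau <- mean(y[b >= 2.0])
    fr0 <- .clamp(plateau, 0.01, 0.9)
    ## excess early decay beyond the hindered rate is attributed to flow
    excess <- if (is.na(sLow)) 0 else max(-sLow - Dh0, 0)
    Df0 <- .clamp(max(excess, 10), lo["Df"], min(hi["Df"], 50))
    ff0 <- .clamp(excess / Df0, 0.02, 0.5)
    rest <- max(1 - fr0 - ff0, 0.05)
    fh0 <- 0.75 * rest
    fui0 <- 0.25 * rest
    fracs <- c(fr = unname(fr0), fh = fh0, fui = fui0, ff = unname(ff0))
    fracs <- fracs / sum(fracs)
    madParameters(Dr = .clamp(0.05, lo["Dr"], hi["Dr"]), Dh = Dh0,
                  Df = Df0, fr = fracs["fr"], fh = fracs["fh"],
                  fui = fracs["fui"], ff = fracs["ff"], alphaH = 1)
}

## Residual and Jacobian of the MAD model in the free parameterization
## (ff = 1 - fr - fh - fui). A penalty row keeps the implied ff >= 0.
.PENALTY <- 50

.madResiduals <- function(theta, b, y) {
    ff <- 1 - theta["fr"] - theta["fh"] - theta["fui"]
    model <- theta["fr"] * exp(-theta["Dr"] * b) +
        theta["fh"] * exp(-theta["Dh"] * b^theta["alphaH"]) +
        theta["fui"] * exp(-.D_UI * b) +
        ff * exp(-theta["Df"] * b)
    c(model - y, .PENALTY * max(0, -ff))
}

.madJacobian <- function(theta, b, y) {
    ff <- 1 - theta["fr"] - theta["fh"] - theta["fui"]
    Er <- exp(-theta["Dr"] * b)
    ba <- b^theta["alphaH"]
    Eh <- exp(-theta["Dh"] * ba)
    Eui <- exp(-.D_UI * b)
    Ef <- exp(-theta["Df"] * b)
    dAlpha <- ifelse(b > 0, -theta["fh"] * theta["Dh"] * ba * log(b) * Eh, 0)
    J <- cbind(Dr = -theta["fr"] * b * Er,
               Dh = -theta["fh"] * ba * Eh,
               Df = -ff * b * Ef,
               alphaH = dAlpha,
               fr = Er - Ef,
               fh = Eh - Ef,
               fui = Eui - Ef)
    pen <- if (ff < 0)
        c(Dr = 0, Dh = 0, Df = 0, alphaH = 0,
          fr = .PENALTY, fh = .PENALTY, fui = .PENALTY)
    else rep(0, 7)
    rbind(J, pen)
}

## Deterministic multistart points: the heuristic start plus seeded
## perturbations (alternating local jitter and box-uniform draws), all
## derived once from the config seed so results never depend on call order.
.multistartPoints <- function(init, config) {
    lo <- config@lower; hi <- config@upper
    n <- config@nMultistart
    starts <- vector("list", n)
    starts[[1]] <- init
    if (n > 1L) {
        .withSeed(config@seed, {
            for (k in 2:n) {
                if (k %% 2L == 0L) {
                    th <- init
                    pos <- c("Dr", "Dh", "Df", "alphaH")
                    th[pos] <- th[pos] * exp(stats::rnorm(4, sd = 0.3))
                    fr3 <- c("fr", "fh", "fui")
                    th[fr3] <- th[fr3] + stats::rnorm(3, sd = 0.08)
                } else {
                    th <- lo + stats::runif(7) * (hi - lo)
                    names(th) <- .FREE_PARAMS
                    th["Df"] <- stats::runif(1, 5, 40)
                }
                th <- .clamp(th, lo, hi)
                s3 <- th["fr"] + th["fh"] + th["fui"]
                if (s3 > 0.98) {
                    sc <- 0.9 / s3
                    th[c("fr", "fh", "fui")] <- th[c("fr", "fh", "fui")] * sc
                }
                starts[[k]] <- th
            }
        })
    }
    starts
}

#' Fit the MAD model to one signal curve
#'
#' Bound-constrained Levenberg-Marquardt least squares over the seven free
#' parameters (Dr, Dh, Df, alphaH and three fractions; the flow fraction is
#' the unit-sum remainder, kept non-negative by a penalty residual; the
#' unimpeded diffusivity is the fixed constant 3 um^2/ms). Multiple starts
#' are run and the lowest residual wins, ties broken by earliest start, so
#' the result is deterministic for a fixed configuration.
#'
#' @param curve a normalized [SignalCurve-class] on a scheme with at least
#'   6 distinct b-values
#' @param config a [FitConfig-class]
#' @return a [MADFitResult-class]; optimizer failure on all starts yields
#'   `converged = FALSE`, not an error
#' @examples
#' truth <- madParameters(Dr = 0.04, Dh = 1.36, Df = 15,
#'                        fr = 0.062, fh = 0.427, fui = 0.284, ff = 0.227,
#'                        alphaH = 0.87)
#' fit <- fitMAD(madSignalCurve(truth, defaultScheme()))
#' paramVector(madParams(fit))
#' @export
fitMAD <- function(curve, config = fitConfig()) {
    stopifnot(is(curve, "SignalCurve"))
    if (!isTRUE(curve@normalized))
        stop("fitMAD requires a normalized curve (S(0) = 1)")
    b <- curve@scheme@bValues
    if (length(unique(b)) < 6L)
        stop("MAD fitting needs at least 6 distinct b-values")
    y <- curve@values
    init <- initializeMAD(curve, config)
    iv <- paramVector(init)
    theta0 <- c(iv["Dr"], iv["Dh"], iv["Df"], iv["alphaH"],
                iv["fr"], iv["fh"], iv["fui"])
    names(theta0) <- .FREE_PARAMS
    starts <- .multistartPoints(theta0, config)

    ctrl <- nls.lm.control(maxiter = config@maxIterations,
                           ftol = config@residualTolerance,
                           ptol = config@relStepTolerance)
    best <- NULL
    bestSS <- Inf
    bestOk <- FALSE
    for (k in seq_along(starts)) {
        ## unlucky starts may exhaust maxiter; that is ordinary multistart
        ## attrition, not a user-facing condition
        fit <- tryCatch(
            suppressWarnings(
                nls.lm(par = starts[[k]], fn = .madResiduals,
                       jac = .madJacobian, b = b, y = y,
                       lower = config@lower, upper = config@upper,
                       control = ctrl)),
            error = function(e) NULL)
        if (is.null(fit)) next
        ok <- fit$info %in% 1:4 && all(is.finite(fit$par))
        ss <- sum(.madResiduals(fit$par, b, y)^2)
        if (is.finite(ss) && ss < bestSS) {   # strict: earliest start wins ties
            bestSS <- ss
            best <- fit
            bestOk <- ok
        }
    }
    if (is.null(best)) {
        return(new("MADFitResult", params = init, residualNorm = Inf,
                   rSquared = 0, converged = FALSE,
                   nStartsTried = length(starts),
                   atBoundFlags = structure(rep(FALSE, 7),
                                            names = .FREE_PARAMS)))
    }
    th <- best$par
    fracs <- c(fr = unname(th["fr"]), fh = unname(th["fh"]),
               fui = unname(th["fui"]),
               ff = max(0, 1 - th["fr"] - th["fh"] - th["fui"]))
    fracs <- fracs / sum(fracs)
    params <- madParameters(Dr = th["Dr"], Dh = th["Dh"], Df = th["Df"],
                            fr = fracs["fr"], fh = fracs["fh"],
                            fui = fracs["fui"], ff = fracs["ff"],
                            alphaH = th["alphaH"])
    resid <- madSignal(params, b) - y
    ssres <- sum(resid^2)
    sstot <- sum((y - mean(y))^2)
    r2 <- if (sstot < 1e-300) as.numeric(ssres < 1e-300)
          else .clamp(1 - ssres / sstot, 0, 1)
    span <- config@upper - config@lower
    atBound <- abs(th - config@lower) < 1e-8 * span |
        abs(th - config@upper) < 1e-8 * span
    names(atBound) <- .FREE_PARAMS
    new("MADFitResult", params = params, residualNorm = sqrt(ssres),
        rSquared = r2, converged = bestOk,
        nStartsTried = length(starts), atBoundFlags = atBound)
}

#' Fit every masked voxel of a 4D volume
#'
#' Each masked voxel is normalized by its own measured S(0), then fitted
#' with [fitMAD()] and [fitADC()]. Voxels outside the mask, with
#' non-positive S(0), or with failed fits hold NaN in every map. The
#' multistart jitter is derived once from the configuration seed, so the
#' result is independent of voxel visit order and bit-reproducible.
#'
#' @param dwi 4D numeric array (x, y, z, b)
#' @param scheme a [BValueScheme-class] matching the 4th dimension
#' @param mask 3D logical array matching the spatial dimensions
#' @param config a [FitConfig-class]
#' @param geometry optional list(dim, pixdim, affine); defaults to unit
#'   voxels with an identity affine
#' @return a [ParameterMaps-class]
#' @export
fitVolume <- function(dwi, scheme, mask, config = fitConfig(),
                      geometry = NULL) {
    d <- dim(dwi)
    if (length(d) != 4L)
        stop("dwi must be a 4D array (x, y, z, b)")
    if (d[4] != length(scheme@bValues))
        stop("4th dimension (", d[4], ") does not match scheme length (",
             length(scheme@bValues), ")")
    if (!identical(as.integer(dim(mask)), as.integer(d[1:3])))
        stop("mask shape does not match spatial dimensions")
    mask <- array(as.logical(mask), dim = d[1:3])
    idx <- which(mask)
    if (length(idx) == 0L)
        stop("degenerate input: empty mask")
    if (is.null(geometry))
        geometry <- list(dim = d[1:3], pixdim = c(1, 1, 1),
                         affine = diag(4))

    maps <- lapply(.MAP_NAMES, function(nm)
        array(.SENTINEL, dim = d[1:3]))
    names(maps) <- .MAP_NAMES
    coords <- arrayInd(idx, d[1:3])
    nvox <- prod(d[1:3])
    for (i in seq_along(idx)) {
        v <- dwi[coords[i, 1], coords[i, 2], coords[i, 3], ]
        s0 <- v[1]
        if (!is.finite(s0) || s0 <= config@minSignalFloor) next
        curve <- signalCurve(v, scheme, normalize = TRUE)
        fit <- tryCatch(fitMAD(curve, config), error = function(e) NULL)
        adc <- tryCatch(fitADC(curve, config), error = function(e) NULL)
        if (is.null(fit) || !fit@converged) {
            maps[["converged"]][idx[i]] <- 0
            next
        }
        pv <- paramVector(fit@params)
        for (nm in .MAD_PARAM_NAMES)
            maps[[nm]][idx[i]] <- pv[nm]
        maps[["ADC"]][idx[i]] <- if (is.null(adc)) .SENTINEL else adc@adc
        maps[["rSquared"]][idx[i]] <- fit@rSquared
        maps[["converged"]][idx[i]] <- 1
    }
    new("ParameterMaps", maps = maps, geometry = geometry)
}
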