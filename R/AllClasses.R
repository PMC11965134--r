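#' @import methods
NULL

## Fixed diffusivity of the unimpeded (free-water-like) compartment, um^2/ms.
## Treating it as a constant avoids collinearity with the upper range of the
## hindered compartment; free water at body temperature diffuses at ~3 um^2/ms.
.D_UI <- 3.0

## Missing-value sentinel used in parameter maps for voxels outside the
## processing mask or with failed fits.
.SENTINEL <- NaN

.MAD_PARAM_NAMES <- c("Dr", "Dh", "Df", "fr", "fh", "fui", "ff", "alphaH")
.COHORT_PARAM_NAMES <- c(.MAD_PARAM_NAMES, "ADC")
.MAP_NAMES <- c(.MAD_PARAM_NAMES, "ADC", "rSquared", "converged")

#' BValueScheme: the diffusion-weighting axis
#'
#' Ordered diffusion weightings (b-values) together with the number of
#' signal averages (NEX) acquired at each weighting. b-values are stored
#' internally in ms/um^2 (1 ms/um^2 = 1000 s/mm^2) so that products D*b of
#' diffusivities in um^2/ms with b are dimensionless.
#'
#' @slot bValues numeric, strictly increasing, first entry exactly 0 (ms/um^2)
#' @slot nAverages integer, one positive count per b-value
#' @export
setClass("BValueScheme",
    representation(bValues = "numeric", nAverages = "integer"),
    validity = function(object) {
        b <- object@bValues
        nav <- object@nAverages
        msg <- character()
        if (length(b) < 1L || b[1] != 0)
            msg <- c(msg, "first b-value must be exactly 0")
        if (length(b) > 1L && any(diff(b) <= 0))
            msg <- c(msg, "b-values must be strictly increasing")
        if (length(nav) != length(b))
            msg <- c(msg, "bValues and nAverages must have equal length")
        if (any(nav < 1L))
            msg <- c(msg, "every nAverages entry must be >= 1")
        if (any(!is.finite(b)))
            msg <- c(msg, "b-values must be finite")
        if (length(msg)) msg else TRUE
    })

#' MADParameters: the nine quantities of the multimodal apparent diffusion model
#'
#' Four compartment diffusivities (restricted, hindered, unimpeded, flow; all
#' um^2/ms), the four corresponding signal fractions (unitless, summing to 1),
#' and the stretching exponent of the hindered compartment.
#'
#' @slot Dr restricted diffusivity, 0 <= Dr < 0.2 um^2/ms
#' @slot Dh hindered diffusivity, 0.2 <= Dh <= 3 um^2/ms
#' @slot Dui unimpeded diffusivity, fixed at 3 um^2/ms
#' @slot Df flow pseudo-diffusivity, 3 < Df <= 100 um^2/ms
#' @slot fr,fh,fui,ff compartment fractions in [0, 1], summing to 1
#' @slot alphaH stretching exponent of the hindered term, 0 < alphaH <= 2
#' @export
setClass("MADParameters",
    representation(Dr = "numeric", Dh = "numeric", Dui = "numeric",
                   Df = "numeric", fr = "numeric", fh = "numeric",
                   fui = "numeric", ff = "numeric", alphaH = "numeric"),
    validity = function(object) {
        msg <- character()
        one <- function(x) length(x) == 1L && is.finite(x)
        vals <- c(object@Dr, object@Dh, object@Dui, object@Df, object@fr,
                  object@fh, object@fui, object@ff, object@alphaH)
        if (length(vals) != 9L || any(!is.finite(vals)))
            return("all nine parameters must be finite scalars")
        if (object@Dr < 0 || object@Dr >= 0.2)
            msg <- c(msg, "Dr must satisfy 0 <= Dr < 0.2")
        if (object@Dh < 0.2 || object@Dh > 3)
            msg <- c(msg, "Dh must satisfy 0.2 <= Dh <= 3")
        if (abs(object@Dui - .D_UI) > 1e-12)
            msg <- c(msg, "Dui is a fixed constant 3.0")
        if (object@Df <= 3 || object@Df > 100)
            msg <- c(msg, "Df must satisfy 3 < Df <= 100")
        fracs <- c(object@fr, object@fh, object@fui, object@ff)
        if (any(fracs < 0) || any(fracs > 1))
            msg <- c(msg, "fractions must lie in [0, 1]")
        if (abs(sum(fracs) - 1) > 1e-9)
            msg <- c(msg, "fractions must sum to 1 within 1e-9")
        if (object@alphaH <= 0 || object@alphaH > 2)
            msg <- c(msg, "alphaH must satisfy 0 < alphaH <= 2")
        if (length(msg)) msg else TRUE
    })

#' SignalCurve: one measured or synthesized diffusion decay
#'
#' @slot scheme the BValueScheme the values sit on
#' @slot values non-negative signal values, one per b-value
#' @slot normalized logical; when TRUE the b = 0 entry equals 1
#' @export
setClass("SignalCurve",
    representation(scheme = "BValueScheme", values = "numeric",
                   normalized = "logical"),
    validity = function(object) {
        msg <- character()
        if (length(object@values) != length(object@scheme@bValues))
            msg <- c(msg, "values and scheme must have equal length")
        if (any(object@values < 0, na.rm = TRUE))
            msg <- c(msg, "signal values must be non-negative")
        if (isTRUE(object@normalized) &&
            abs(object@values[1] - 1) > 1e-12)
            msg <- c(msg, "normalized curve must have values[1] == 1 within 1e-12")
        if (length(msg)) msg else TRUE
    })

#' ADCFit: a mono-exponential (log-linear) fit
#'
#' `adc` is minus the OLS slope of log signal on b. Negative ADC estimates
#' (positive slopes, possible in noise) are reported but flagged unphysical.
#'
#' @slot adc apparent diffusion coefficient, um^2/ms
#' @slot intercept fitted log-signal at b = 0
#' @slot rSquared coefficient of determination of the log-linear fit
#' @slot nPointsUsed points entering the fit after the signal-floor cut
#' @slot physical TRUE when adc >= 0
#' @export
setClass("ADCFit",
    representation(adc = "numeric", intercept = "numeric",
                   rSquared = "numeric", nPointsUsed = "integer",
                   physical = "logical"),
    validity = function(object) {
        msg <- character()
        if (!is.na(object@rSquared) &&
            (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
            msg <- c(msg, "rSquared must lie in [0, 1]")
        if (object@nPointsUsed < 2L)
            msg <- c(msg, "at least 2 points are needed for a slope")
        if (length(msg)) msg else TRUE
    })

#' FitConfig: optimizer settings for MAD and ADC fitting
#'
#' @slot lower,upper named bounds for the free parameters
#'   (Dr, Dh, Df, alphaH, fr, fh, fui); defaults reproduce the
#'   MADParameters invariants
#' @slot nMultistart number of optimizer starts (>= 1); the first start is
#'   the segmented log-linear heuristic, the rest are seeded perturbations
#' @slot maxIterations,residualTolerance,relStepTolerance Levenberg-Marquardt
#'   controls
#' @slot seed integer seed for the start-point jitter
#' @slot minSignalFloor signals at or below this fraction of S(0) are
#'   excluded from log-linear fits
#' @export
setClass("FitConfig",
    representation(lower = "numeric", upper = "numeric",
                   nMultistart = "integer", maxIterations = "integer",
                   residualTolerance = "numeric",
                   relStepTolerance = "numeric", seed = "integer",
                   minSignalFloor = "numeric"),
    validity = function(object) {
        msg <- character()
        need <- c("Dr", "Dh", "Df", "alphaH", "fr", "fh", "fui")
        if (!all(need %in% names(object@lower)) ||
            !all(need %in% names(object@upper)))
            msg <- c(msg, "lower/upper must name Dr, Dh, Df, alphaH, fr, fh, fui")
        if (object@nMultistart < 1L)
            msg <- c(msg, "nMultistart must be >= 1")
        if (object@residualTolerance <= 0 || object@relStepTolerance <= 0)
            msg <- c(msg, "tolerances must be > 0")
        if (length(msg)) msg else TRUE
    })

#' MADFitResult: one voxel's constrained least-squares fit
#'
#' @slot params the fitted MADParameters
#' @slot residualNorm Euclidean norm of the model-data residual
#' @slot rSquared coefficient of determination over the curve
#' @slot converged FALSE marks fits that must not enter downstream summaries
#' @slot nStartsTried number of optimizer starts actually run
#' @slot atBoundFlags named logicals, TRUE where a free parameter sits on a bound
#' @export
setClass("MADFitResult",
    representation(params = "MADParameters", residualNorm = "numeric",
                   rSquared = "numeric", converged = "logical",
                   nStartsTried = "integer", atBoundFlags = "logical"),
    validity = function(object) {
        if (is.finite(object@residualNorm) && object@residualNorm < 0)
            "residualNorm must be >= 0" else TRUE
    })

#' ParameterMaps: voxel-wise grids of fitted quantities
#'
#' One 3D array per quantity (the eight MAD parameters, ADC, rSquared and a
#' converged indicator), sharing a spatial geometry. Voxels outside the
#' processing mask or with failed fits hold NaN.
#'
#' @slot maps named list of 3D arrays
#' @slot geometry list with elements `dim` (spatial dims), `pixdim`
#'   (voxel size) and `affine` (4x4 voxel-to-world matrix)
#' @export
setClass("ParameterMaps",
    representation(maps = "list", geometry = "list"),
    validity = function(object) {
        msg <- character()
        if (!all(.MAP_NAMES %in% names(object@maps)))
            msg <- c(msg, paste("maps must contain:",
                                paste(.MAP_NAMES, collapse = ", ")))
        dims <- lapply(object@maps, dim)
        if (length(unique(lapply(dims, as.integer))) > 1L)
            msg <- c(msg, "all maps must share the same shape")
        if (length(msg)) msg else TRUE
    })

#' GradeParameterDistribution: per-grade generating distribution
#'
#' Independent truncated normals per parameter (eight MAD quantities plus
#' ADC); fraction means are renormalized to unit sum before use.
#'
#' @slot grade "low" or "high"
#' @slot means,sds named numeric vectors over Dr, Dh, Df, fr, fh, fui, ff,
#'   alphaH, ADC
#' @export
setClass("GradeParameterDistribution",
    representation(grade = "character", means = "numeric", sds = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!object@grade %in% c("low", "high"))
            msg <- c(msg, "grade must be 'low' or 'high'")
        if (!all(.COHORT_PARAM_NAMES %in% names(object@means)) ||
            !all(.COHORT_PARAM_NAMES %in% names(object@sds)))
            msg <- c(msg, "means/sds must name all nine parameters")
        if (any(object@sds < 0))
            msg <- c(msg, "SDs must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' NoiseConfig: Rician measurement-noise settings
#'
#' @slot sigma per-channel Gaussian noise scale relative to S(0)
#' @slot applyAveraging average nAverages independent magnitude draws per b
#' @slot gaussian use additive Gaussian noise instead of Rician (debug aid)
#' @slot seed integer seed
#' @export
setClass("NoiseConfig",
    representation(sigma = "numeric", applyAveraging = "logical",
                   gaussian = "logical", seed = "integer"),
    validity = function(object) {
        if (object@sigma < 0) "sigma must be >= 0" else TRUE
    })

#' PhantomTruth: ground truth attached to a synthetic phantom
#'
#' @slot truthMaps named list of 3D arrays of generating parameter values
#'   (NaN on background)
#' @slot labels 3D integer array: 0 background, 1 low-grade, 2 high-grade
#' @export
setClass("PhantomTruth",
    representation(truthMaps = "list", labels = "array"),
    validity = function(object) {
        lesion <- object@labels != 0L
        for (nm in names(object@truthMaps)) {
            tm <- object@truthMaps[[nm]]
            if (!identical(dim(tm), dim(object@labels)))
                return("truth maps and labels must share shape")
            if (any(!is.finite(tm[lesion])))
                return("truth must be defined wherever label != background")
        }
        TRUE
    })

#' MADCohort: per-subject ROI-mean parameters with grade labels
#'
#' @slot table data.frame with columns subject, grade, the nine parameters
#'   and nVoxels
#' @slot provenance list: source ("real" or "synthetic") and seed
#' @export
setClass("MADCohort",
    representation(table = "data.frame", provenance = "list"),
    validity = function(object) {
        tab <- object@table
        msg <- character()
        need <- c("subject", "grade", .COHORT_PARAM_NAMES, "nVoxels")
        if (!all(need %in% names(tab)))
            msg <- c(msg, paste("cohort table must have columns:",
                                paste(need, collapse = ", ")))
        else {
            if (anyDuplicated(tab$subject))
                msg <- c(msg, "subject ids must be unique")
            if (!all(tab$grade %in% c("low", "high")))
                msg <- c(msg, "grade must be 'low' or 'high'")
            fr <- as.matrix(tab[, c("fr", "fh", "fui", "ff")])
            if (any(fr < -1e-9 | fr > 1 + 1e-9))
                msg <- c(msg, "fractions must lie in [0, 1]")
            if (any(tab$nVoxels < 1L))
                msg <- c(msg, "nVoxels must be >= 1")
        }
        if (length(msg)) msg else TRUE
    })

#' GroupComparison: one parameter's two-group test
#'
#' @slot parameter quantity name
#' @slot summaryLow,summaryHigh formatted per-group summaries (mean +/- SD
#'   for the t route, median (IQR) for the rank route)
#' @slot normalityP KS normality p-values, one per group
#' @slot varianceP F-test p-value for equal variances
#' @slot testUsed "t" or "mann-whitney"
#' @slot pValue two-sided p
#' @slot cohensD pooled-SD effect size
#' @slot significant pValue < 0.05
#' @export
setClass("GroupComparison",
    representation(parameter = "character", summaryLow = "character",
                   summaryHigh = "character", normalityP = "numeric",
                   varianceP = "numeric", testUsed = "character",
                   pValue = "numeric", cohensD = "numeric",
                   significant = "logical"),
    validity = function(object) {
        msg <- character()
        if (!is.na(object@pValue) &&
            (object@pValue < 0 || object@pValue > 1))
            msg <- c(msg, "pValue must lie in [0, 1]")
        if (!object@testUsed %in% c("t", "mann-whitney"))
            msg <- c(msg, "testUsed must be 't' or 'mann-whitney'")
        if (length(msg)) msg else TRUE
    })

#' ROCResult: an empirical ROC curve with optional CI and operating point
#'
#' @slot name score or model name
#' @slot fpr,tpr curve points from (0,0) to (1,1)
#' @slot auc trapezoid area under the curve (orientation-corrected, >= 0.5
#'   for informative scores)
#' @slot ciLow,ciHigh DeLong 95 percent interval, clipped to [0, 1] (NA until computed)
#' @slot threshold,sensitivity,specificity,accuracy Youden operating point
#'   (NA until computed)
#' @slot higherIsPositive TRUE when larger scores indicate the positive
#'   (high-grade) class
#' @export
setClass("ROCResult",
    representation(name = "character", fpr = "numeric", tpr = "numeric",
                   auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   threshold = "numeric", sensitivity = "numeric",
                   specificity = "numeric", accuracy = "numeric",
                   higherIsPositive = "logical"),
    validity = function(object) {
        msg <- character()
        if (object@auc < 0 || object@auc > 1)
            msg <- c(msg, "auc must lie in [0, 1]")
        n <- length(object@fpr)
        if (length(object@tpr) != n)
            msg <- c(msg, "fpr and tpr must have equal length")
        else {
            if (abs(object@fpr[1]) > 1e-12 || abs(object@tpr[1]) > 1e-12 ||
                abs(object@fpr[n] - 1) > 1e-12 || abs(object@tpr[n] - 1) > 1e-12)
                msg <- c(msg, "ROC points must start at (0,0) and end at (1,1)")
            if (any(diff(object@fpr) < -1e-12) || any(diff(object@tpr) < -1e-12))
                msg <- c(msg, "ROC points must be non-decreasing")
        }
        for (s in c("sensitivity", "specificity", "accuracy"))
            if (!is.na(slot(object, s)) &&
                (slot(object, s) < 0 || slot(object, s) > 1))
                msg <- c(msg, paste(s, "must lie in [0, 1]"))
        if (length(msg)) msg else TRUE
    })

#' LogisticModel: a fitted (possibly ridge-stabilized) logistic classifier
#'
#' @slot features feature names
#' @slot coefficients named vector: (Intercept) then one per feature, on the
#'   original feature scale
#' @slot converged FALSE when the ML fit separated or failed and the ridge
#'   fallback was used
#' @slot ridged TRUE when the ridge fallback produced the coefficients
#' @slot probabilities in-sample predicted P(high grade), input order
#' @export
setClass("LogisticModel",
    representation(features = "character", coefficients = "numeric",
                   converged = "logical", ridged = "logical",
                   probabilities = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@coefficients) != length(object@features) + 1L)
            msg <- c(msg, "coefficient count must equal feature count + 1")
        if (any(object@probabilities <= 0 | object@probabilities >= 1))
            msg <- c(msg, "probabilities must lie strictly in (0, 1)")
        if (length(msg)) msg else TRUE
    })
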