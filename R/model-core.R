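#' @include AllClasses.R
NULL

#' Construct a b-value scheme
#'
#' @param bValues numeric b-values. Interpreted in s/mm^2 when
#'   `units = "s/mm2"` (the usual scanner convention) and converted to the
#'   internal ms/um^2; pass `units = "ms/um2"` for already-converted values.
#' @param nAverages integer averaging counts (NEX), recycled to length 1
#'   meaning "one average everywhere".
#' @param units unit of `bValues`
#' @return a [BValueScheme-class]
#' @examples
#' bValueScheme(c(0, 500, 1000, 2000), c(1, 2, 3, 6))
#' @export
bValueScheme <- function(bValues, nAverages = 1L,
                         units = c("s/mm2", "ms/um2")) {
    units <- match.arg(units)
    if (units == "s/mm2") bValues <- bFromSmm2(bValues)
    if (length(nAverages) == 1L)
        nAverages <- rep(nAverages, length(bValues))
    new("BValueScheme", bValues = as.numeric(bValues),
        nAverages = as.integer(nAverages))
}

#' Construct a MAD parameter set
#'
#' The unimpeded diffusivity is a fixed model constant (3 um^2/ms) and is
#' not an argument. Fractions must sum to 1; use `renormalizeFractions()`
#' to prepare literature means that do not.
#'
#' @param Dr,Dh,Df diffusivities in um^2/ms
#' @param fr,fh,fui,ff compartment fractions
#' @param alphaH stretching exponent of the hindered compartment
#' @return a validated [MADParameters-class]
#' @export
madParameters <- function(Dr, Dh, Df, fr, fh, fui, ff, alphaH) {
    new("MADParameters", Dr = as.numeric(Dr), Dh = as.numeric(Dh),
        Dui = .D_UI, Df = as.numeric(Df), fr = as.numeric(fr),
        fh = as.numeric(fh), fui = as.numeric(fui), ff = as.numeric(ff),
        alphaH = as.numeric(alphaH))
}

#' Rescale compartment fractions to unit sum
#'
#' Published ROI-mean fractions rarely sum exactly to 1 (each map is averaged
#' independently). For signal synthesis the four fractions must; this either
#' rescales all four proportionally, or holds one at its stated value and
#' rescales the remaining three to complete the sum.
#'
#' @param fractions named numeric over fr, fh, fui, ff
#' @param hold optional name of one fraction to keep at its stated value
#' @return named numeric summing to 1
#' @export
renormalizeFractions <- function(fractions, hold = NULL) {
    need <- c("fr", "fh", "fui", "ff")
    if (!all(need %in% names(fractions)))
        stop("fractions must name fr, fh, fui, ff")
    fractions <- fractions[need]
    if (is.null(hold)) return(fractions / sum(fractions))
    hold <- match.arg(hold, need)
    rest <- setdiff(need, hold)
    if (fractions[hold] >= 1)
        stop("held fraction must be < 1")
    fractions[rest] <- fractions[rest] * (1 - fractions[hold]) /
        sum(fractions[rest])
    fractions
}

#' Evaluate the MAD forward model
#'
#' The normalized diffusion signal is a sum of four decaying compartments:
#' restricted, hindered (stretched-exponential in b), unimpeded and flow:
#' \deqn{S(b)/S(0) = f_r e^{-D_r b} + f_h e^{-D_h b^{\alpha_h}} +
#'   f_{ui} e^{-D_{ui} b} + f_f e^{-D_f b}.}
#' Only the hindered term carries the stretching exponent; b is in ms/um^2
#' so every exponent is dimensionless.
#'
#' @param params a [MADParameters-class]
#' @param b non-negative b-value(s) in ms/um^2
#' @return normalized signal in (0, 1], vectorized over `b`
#' @examples
#' p <- madParameters(Dr = 0.04, Dh = 1.4, Df = 15,
#'                    fr = 0.06, fh = 0.44, fui = 0.28, ff = 0.22,
#'                    alphaH = 0.9)
#' madSignal(p, c(0, 0.8, 3))
#' @export
madSignal <- function(params, b) {
    stopifnot(is(params, "MADParameters"))
    validObject(params)
    if (any(b < 0)) stop("b must be >= 0")
    params@fr * exp(-params@Dr * b) +
        params@fh * exp(-params@Dh * b^params@alphaH) +
        params@fui * exp(-params@Dui * b) +
        params@ff * exp(-params@Df * b)
}

#' Evaluate the MAD model over a whole scheme
#'
#' @param params a [MADParameters-class]
#' @param scheme a [BValueScheme-class]
#' @return a normalized [SignalCurve-class]
#' @export
madSignalCurve <- function(params, scheme) {
    stopifnot(is(scheme, "BValueScheme"))
    validObject(scheme)
    new("SignalCurve", scheme = scheme,
        values = madSignal(params, scheme@bValues), normalized = TRUE)
}

#' Mono-exponential (ADC) forward model
#'
#' @param adc apparent diffusion coefficient, um^2/ms, >= 0
#' @param b b-value(s) in ms/um^2, >= 0
#' @return exp(-adc * b)
#' @export
monoSignal <- function(adc, b) {
    if (any(adc < 0)) stop("adc must be >= 0")
    if (any(b < 0)) stop("b must be >= 0")
    exp(-adc * b)
}

#' Wrap raw measurements as a signal curve
#'
#' @param values signal values, one per b-value of `scheme`
#' @param scheme a [BValueScheme-class]
#' @param normalize divide by the b = 0 entry
#' @return a [SignalCurve-class]
#' @export
signalCurve <- function(values, scheme, normalize = FALSE) {
    if (normalize) {
        s0 <- values[1]
        if (!is.finite(s0) || s0 <= 0)
            stop("cannot normalize: S(0) must be > 0")
        values <- values / s0
    }
    new("SignalCurve", scheme = scheme, values = as.numeric(values),
        normalized = isTRUE(normalize) ||
            isTRUE(abs(values[1] - 1) <= 1e-12))
}
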