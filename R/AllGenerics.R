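#' @include AllClasses.R
NULL

#' Accessors for madmri classes
#'
#' Small getters so user code never touches slots directly.
#'
#' @param object a madmri object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("nAverages", function(object) standardGeneric("nAverages"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("bScheme", function(object) standardGeneric("bScheme"))

#' @rdname accessors
#' @export
setGeneric("madParams", function(object) standardGeneric("madParams"))

#' @rdname accessors
#' @export
setGeneric("paramVector", function(object) standardGeneric("paramVector"))

#' @rdname accessors
#' @export
setGeneric("paramMap", function(object, name) standardGeneric("paramMap"))

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))

#' @rdname accessors
#' @export
setMethod("bValues", "BValueScheme", function(object) object@bValues)

#' @rdname accessors
#' @export
setMethod("nAverages", "BValueScheme", function(object) object@nAverages)

#' @rdname accessors
#' @export
setMethod("signalValues", "SignalCurve", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("bScheme", "SignalCurve", function(object) object@scheme)

#' @rdname accessors
#' @export
setMethod("madParams", "MADFitResult", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("paramVector", "MADParameters", function(object) {
    c(Dr = object@Dr, Dh = object@Dh, Dui = object@Dui, Df = object@Df,
      fr = object@fr, fh = object@fh, fui = object@fui, ff = object@ff,
      alphaH = object@alphaH)
})

#' @rdname accessors
#' @export
setMethod("paramMap", "ParameterMaps", function(object, name) {
    if (!name %in% names(object@maps))
        stop("no map named '", name, "'; available: ",
             paste(names(object@maps), collapse = ", "))
    object@maps[[name]]
})

#' @rdname accessors
#' @export
setMethod("cohortTable", "MADCohort", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("provenance", "MADCohort", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("aucValue", "ROCResult", function(object) object@auc)

setMethod("show", "BValueScheme", function(object) {
    cat("BValueScheme with", length(object@bValues), "b-values (ms/um^2)\n")
    cat("  b:  ", paste(format(object@bValues), collapse = " "), "\n")
    cat("  NEX:", paste(object@nAverages, collapse = " "), "\n")
})

setMethod("show", "MADParameters", function(object) {
    v <- paramVector(object)
    cat("MADParameters\n")
    cat(sprintf("  diffusivities (um^2/ms): Dr=%.4g Dh=%.4g Dui=%.4g Df=%.4g\n",
                v["Dr"], v["Dh"], v["Dui"], v["Df"]))
    cat(sprintf("  fractions: fr=%.4g fh=%.4g fui=%.4g ff=%.4g (sum %.6f)\n",
                v["fr"], v["fh"], v["fui"], v["ff"],
                sum(v[c("fr", "fh", "fui", "ff")])))
    cat(sprintf("  alphaH=%.4g\n", v["alphaH"]))
})

setMethod("show", "SignalCurve", function(object) {
    cat("SignalCurve on", length(object@values), "b-values",
        if (object@normalized) "(normalized)" else "(raw)", "\n")
    cat("  values:", paste(format(object@values, digits = 4), collapse = " "),
        "\n")
})

setMethod("show", "MADFitResult", function(object) {
    cat("MADFitResult:", if (object@converged) "converged" else "NOT converged",
        sprintf("(residual %.3g, R^2 %.4f, %d starts)\n",
                object@residualNorm, object@rSquared, object@nStartsTried))
    show(object@params)
})

setMethod("show", "ParameterMaps", function(object) {
    d <- dim(object@maps[[1]])
    nfit <- sum(is.finite(object@maps[["Dh"]]))
    cat("ParameterMaps", paste(d, collapse = " x "),
        "with", length(object@maps), "quantities;",
        nfit, "fitted voxels\n")
})

setMethod("show", "MADCohort", function(object) {
    tab <- object@table
    cat("MADCohort:", nrow(tab), "subjects (",
        sum(tab$grade == "low"), "low-grade,",
        sum(tab$grade == "high"), "high-grade );",
        "source:", object@provenance$source, "\n")
})

setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("GroupComparison [%s] %s vs %s: %s test, p = %.4g%s, d = %.3f\n",
                object@parameter, object@summaryLow, object@summaryHigh,
                object@testUsed, object@pValue,
                if (isTRUE(object@significant)) " *" else "",
                object@cohensD))
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult [%s] AUC = %.3f", object@name, object@auc))
    if (!is.na(object@ciLow))
        cat(sprintf(" (95%% CI %.3f-%.3f)", object@ciLow, object@ciHigh))
    if (!is.na(object@threshold))
        cat(sprintf("; Youden: thr %.4g, sens %.3f, spec %.3f, acc %.3f",
                    object@threshold, object@sensitivity,
                    object@specificity, object@accuracy))
    cat("\n")
})

setMethod("show", "LogisticModel", function(object) {
    cat("LogisticModel over", paste(object@features, collapse = " + "),
        if (object@ridged) "(ridge-stabilized)" else "", "\n")
    print(round(object@coefficients, 4))
})
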