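#' @include AllClasses.R fitting.R
NULL

#' Mean of a parameter map over an ROI mask
#'
#' Arithmetic mean over masked voxels, excluding missing-value (NaN)
#' sentinel voxels from failed or masked-out fits; the number of voxels
#' actually used is returned alongside.
#'
#' @param map 3D numeric array
#' @param mask 3D logical array of the same shape
#' @return list(mean, nVoxels)
#' @export
roiMean <- function(map, mask) {
    if (!identical(as.integer(dim(map)), as.integer(dim(mask))))
        stop("map and mask shapes differ")
    vals <- map[as.logical(mask)]
    if (length(vals) == 0L)
        stop("degenerate input: empty mask")
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L)
        stop("degenerate input: no valid (non-sentinel) voxels under mask")
    list(mean = mean(vals), nVoxels = length(vals))
}

#' One subject's ROI-mean record
#'
#' @param subject subject identifier
#' @param grade "low" or "high"
#' @param params named numeric over Dr, Dh, Df, fr, fh, fui, ff, alphaH, ADC
#' @param nVoxels voxels contributing to the means
#' @return a one-row data.frame in the cohort-table layout
#' @export
subjectRecord <- function(subject, grade, params, nVoxels) {
    stopifnot(all(.COHORT_PARAM_NAMES %in% names(params)), nVoxels >= 1L)
    cbind(data.frame(subject = subject, grade = grade,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(params[.COHORT_PARAM_NAMES])),
          data.frame(nVoxels = as.integer(nVoxels)))
}

#' Merge two readers' measurements of the same subject
#'
#' The per-parameter arithmetic mean of the two records; commutative and
#' idempotent on identical inputs. Voxel counts are averaged (rounded up).
#'
#' @param recordA,recordB one-row records from [subjectRecord()] or
#'   [extractSubject()], same subject and grade
#' @return a merged one-row record
#' @export
combineReaders <- function(recordA, recordB) {
    if (!identical(recordA$subject, recordB$subject))
        stop("subject-id mismatch: '", recordA$subject, "' vs '",
             recordB$subject, "'")
    if (!identical(recordA$grade, recordB$grade))
        stop("grade mismatch for subject '", recordA$subject, "'")
    out <- recordA
    for (nm in .COHORT_PARAM_NAMES)
        out[[nm]] <- (recordA[[nm]] + recordB[[nm]]) / 2
    out$nVoxels <- as.integer(ceiling((recordA$nVoxels + recordB$nVoxels) / 2))
    out
}

#' Extract one subject's record from fitted maps
#'
#' Computes ROI means of every parameter map under each reader's mask and
#' merges the (one or two) readers with [combineReaders()].
#'
#' @param maps a [ParameterMaps-class]
#' @param masks list of one or two 3D logical arrays (one per reader)
#' @param subject subject identifier
#' @param grade "low" or "high"
#' @return a one-row record
#' @export
extractSubject <- function(maps, masks, subject, grade) {
    if (length(masks) < 1L || length(masks) > 2L)
        stop("one or two reader masks are required")
    one <- function(mask) {
        vals <- vapply(.COHORT_PARAM_NAMES, function(nm)
            roiMean(paramMap(maps, nm), mask)$mean, numeric(1))
        nv <- roiMean(paramMap(maps, "Dh"), mask)$nVoxels
        subjectRecord(subject, grade, vals, nv)
    }
    recs <- lapply(masks, one)
    if (length(recs) == 1L) recs[[1]] else
        combineReaders(recs[[1]], recs[[2]])
}

#' Assemble subject records into a cohort
#'
#' @param records list of one-row records
#' @param source provenance label ("real" or "synthetic")
#' @param seed seed recorded in the provenance (NA for real data)
#' @return a [MADCohort-class]
#' @export
cohortFromRecords <- function(records, source = "real", seed = NA_integer_) {
    tab <- do.call(rbind, records)
    rownames(tab) <- NULL
    new("MADCohort", table = tab,
        provenance = list(source = source, seed = seed))
}
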