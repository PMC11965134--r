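#' @include AllClasses.R fitting.R synthetic-data.R roi-analysis.R
#' @include group-stats.R classification.R
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Read a 4D diffusion-weighted volume with its b-value table
#'
#' The b-table is one-line whitespace-separated text in s/mm^2 (the common
#' diffusion-toolkit convention); values are converted to the internal
#' ms/um^2. An averaging-count file is read from `averagesPath`, or from
#' `<btablePath>.nex` when that exists; otherwise every NEX is 1.
#'
#' @param dwiPath NIfTI file with a 4D volume (x, y, z, b)
#' @param btablePath b-value text file, one entry per volume
#' @param averagesPath optional averaging-count text file
#' @return list(dwi = 4D array, scheme = [BValueScheme-class],
#'   geometry = list(dim, pixdim, affine, reference))
#' @export
readDWI <- function(dwiPath, btablePath, averagesPath = NULL) {
    if (!file.exists(dwiPath)) stop("DWI file not found: ", dwiPath)
    if (!file.exists(btablePath)) stop("b-table not found: ", btablePath)
    img <- RNifti::readNifti(dwiPath)
    arr <- as.array(img)
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    b <- scan(btablePath, quiet = TRUE)
    if (length(b) != dim(arr)[4])
        stop("b-table has ", length(b), " entries but the volume has ",
             dim(arr)[4], " b-volumes")
    if (is.null(averagesPath) && file.exists(paste0(btablePath, ".nex")))
        averagesPath <- paste0(btablePath, ".nex")
    nav <- if (!is.null(averagesPath)) {
        v <- scan(averagesPath, quiet = TRUE)
        if (length(v) != length(b))
            stop("averages file has ", length(v), " entries but the ",
                 "b-table has ", length(b))
        as.integer(v)
    } else rep(1L, length(b))
    scheme <- bValueScheme(b, nav, units = "s/mm2")
    geometry <- list(dim = dim(arr)[1:3],
                     pixdim = unname(RNifti::pixdim(img))[1:3],
                     affine = unclass(RNifti::xform(img)),
                     reference = RNifti::niftiHeader(img))
    list(dwi = arr, scheme = scheme, geometry = geometry)
}

#' Write a b-value scheme as text files
#'
#' Writes `path` (b-values in s/mm^2, one line, whitespace-separated) and
#' `<path>.nex` (the averaging counts).
#'
#' @param scheme a [BValueScheme-class]
#' @param path output path for the b-table
#' @return invisibly, the two paths written
#' @export
writeScheme <- function(scheme, path) {
    writeLines(paste(format(bToSmm2(scheme@bValues), trim = TRUE,
                            scientific = FALSE), collapse = " "), path)
    writeLines(paste(scheme@nAverages, collapse = " "),
               paste0(path, ".nex"))
    invisible(c(path, paste0(path, ".nex")))
}

#' Read/write a cohort as CSV
#'
#' One row per subject, columns: subject, grade, the nine parameters,
#' nVoxels.
#'
#' @param cohort a [MADCohort-class]
#' @param path CSV path
#' @return `readCohortCSV` returns a [MADCohort-class]
#' @export
writeCohortCSV <- function(cohort, path) {
    utils::write.csv(cohortTable(cohort), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCohortCSV
#' @param source,seed provenance recorded on read
#' @export
readCohortCSV <- function(path, source = "real", seed = NA_integer_) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    new("MADCohort", table = tab,
        provenance = list(source = source, seed = seed))
}

## Write one 3D map as NIfTI, carrying the input geometry when available.
.writeMap <- function(arr, path, geometry) {
    img <- if (!is.null(geometry$reference))
        RNifti::asNifti(arr, reference = geometry$reference)
    else RNifti::asNifti(arr)
    RNifti::writeNifti(img, path)
    path
}

#' Write analysis outputs and a reproducibility manifest
#'
#' Parameter maps become one NIfTI file per quantity (input affine
#' preserved when present); tables become CSV; ROC results JSON. The
#' manifest records every written file, the seed, the package version and
#' an MD5 hash of the configuration.
#'
#' @param outputDir writable directory (created if needed)
#' @param maps optional [ParameterMaps-class]
#' @param cohort optional [MADCohort-class]
#' @param comparisons optional result of [summarizeComparisons()]
#' @param diagnostics optional result of [diagnosticTable()]
#' @param clinical optional result of [clinicalSummary()]
#' @param config optional configuration object (hashed into the manifest)
#' @param seed seed recorded in the manifest
#' @return the manifest, invisibly (also written as manifest.json)
#' @export
writeOutputs <- function(outputDir, maps = NULL, cohort = NULL,
                         comparisons = NULL, diagnostics = NULL,
                         clinical = NULL, config = NULL,
                         seed = NA_integer_) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    wr <- function(p) { files <<- c(files, basename(p)); p }
    if (!is.null(maps)) {
        for (nm in names(maps@maps))
            .writeMap(maps@maps[[nm]],
                      wr(file.path(outputDir, paste0("map_", nm, ".nii.gz"))),
                      maps@geometry)
    }
    if (!is.null(cohort))
        writeCohortCSV(cohort, wr(file.path(outputDir, "cohort.csv")))
    if (!is.null(comparisons))
        utils::write.csv(comparisons$table,
                         wr(file.path(outputDir, "group_comparisons.csv")),
                         row.names = FALSE)
    if (!is.null(diagnostics)) {
        utils::write.csv(diagnostics$table,
                         wr(file.path(outputDir, "diagnostic_table.csv")),
                         row.names = FALSE)
        rocJson <- lapply(diagnostics$rocs, function(r)
            list(name = r@name, auc = r@auc, ciLow = r@ciLow,
                 ciHigh = r@ciHigh, threshold = r@threshold,
                 sensitivity = r@sensitivity, specificity = r@specificity,
                 accuracy = r@accuracy, fpr = r@fpr, tpr = r@tpr))
        jsonlite::write_json(rocJson,
                             wr(file.path(outputDir, "roc_results.json")),
                             auto_unbox = TRUE, digits = NA)
    }
    if (!is.null(clinical)) {
        utils::write.csv(clinical$categories,
                         wr(file.path(outputDir, "clinical_summary.csv")),
                         row.names = FALSE)
    }
    configHash <- NA_character_
    if (!is.null(config)) {
        tmp <- tempfile(fileext = ".json")
        jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE)
        configHash <- unname(tools::md5sum(tmp))
        unlink(tmp)
    }
    manifest <- list(files = as.list(files), seed = seed,
                     configHash = configHash,
                     package = "madmri",
                     version = as.character(utils::packageVersion("madmri")))
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}

#' Assemble a pipeline configuration
#'
#' @param mode "simulate" (synthetic cohort) or "real" (read files)
#' @param outputDir where outputs and the manifest go
#' @param seed master seed; every random stage derives from it
#' @param nLow,nHigh simulate-mode group sizes
#' @param features parameters combined in the logistic model
#' @param subjectsPath real-mode CSV with columns subject, grade, dwi,
#'   btable, mask1 and optional mask2 (file paths per subject)
#' @param fitConfig a [FitConfig-class] for real-mode voxel fitting
#' @param verbose log stage progress to stderr
#' @return a configuration list of class "madPipelineConfig"
#' @export
pipelineConfig <- function(mode = c("simulate", "real"),
                           outputDir = tempfile("madmri_out"),
                           seed = 1L, nLow = 30L, nHigh = 24L,
                           features = c("Dh", "fr", "alphaH"),
                           subjectsPath = NULL,
                           fitConfig = madmri::fitConfig(),
                           verbose = FALSE) {
    mode <- match.arg(mode)
    if (mode == "real") {
        if (is.null(subjectsPath) || !file.exists(subjectsPath))
            stop("real mode requires an existing subjectsPath CSV")
    }
    structure(list(mode = mode, outputDir = outputDir,
                   seed = as.integer(seed), nLow = as.integer(nLow),
                   nHigh = as.integer(nHigh), features = features,
                   subjectsPath = subjectsPath, fitConfig = fitConfig,
                   verbose = verbose),
              class = "madPipelineConfig")
}

## Synthetic per-subject demographics for simulate-mode clinical tables.
.simulateMetadata <- function(cohort, seed) {
    tab <- cohortTable(cohort)
    .withSeed(.childSeed(seed, 77L), {
        data.frame(subject = tab$subject, grade = tab$grade,
                   age = sample(38:76, nrow(tab), replace = TRUE),
                   sex = sample(c("male", "female"), nrow(tab),
                                replace = TRUE, prob = c(0.7, 0.3)),
                   stringsAsFactors = FALSE)
    })
}

.logStage <- function(verbose, ...) if (verbose) message("[madmri] ", ...)

#' Run the full analysis pipeline
#'
#' Simulate mode: draw a synthetic cohort, run the group comparisons
#' (nine-parameter table), the per-parameter and combined ROC analysis, a
#' clinical summary over simulated demographics, and write all outputs.
#' Real mode: per subject, read the DWI and masks, fit every masked voxel,
#' extract ROI means (merging two readers when present), then the same
#' statistical chain.
#'
#' @param config a configuration from [pipelineConfig()]
#' @return report list(cohort, comparisons, diagnostics, clinical, manifest)
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "madPipelineConfig"))
    v <- config$verbose
    if (config$mode == "simulate") {
        .logStage(v, "simulating cohort (", config$nLow, " low / ",
                  config$nHigh, " high, seed ", config$seed, ")")
        cohort <- makeCohort(config$nLow, config$nHigh, seed = config$seed)
        maps <- NULL
    } else {
        subjects <- utils::read.csv(config$subjectsPath,
                                    stringsAsFactors = FALSE)
        need <- c("subject", "grade", "dwi", "btable", "mask1")
        if (!all(need %in% names(subjects)))
            stop("subjects CSV must have columns: ",
                 paste(need, collapse = ", "))
        records <- vector("list", nrow(subjects))
        maps <- NULL
        for (i in seq_len(nrow(subjects))) {
            row <- subjects[i, ]
            .logStage(v, "fitting subject ", row$subject)
            rec <- tryCatch({
                inp <- readDWI(row$dwi, row$btable)
                masks <- list(.as3DArray(as.array(
                    RNifti::readNifti(row$mask1)) > 0))
                if ("mask2" %in% names(row) && !is.na(row$mask2) &&
                    nzchar(row$mask2))
                    masks <- c(masks, list(.as3DArray(as.array(
                        RNifti::readNifti(row$mask2)) > 0)))
                fitMask <- Reduce(`|`, masks)
                m <- fitVolume(inp$dwi, inp$scheme, fitMask,
                               config$fitConfig, geometry = inp$geometry)
                maps <- m   # last subject's maps kept for output
                extractSubject(m, masks, row$subject, row$grade)
            }, error = function(e)
                stop("stage 'fit' failed for subject '", row$subject,
                     "': ", conditionMessage(e)))
            records[[i]] <- rec
        }
        cohort <- cohortFromRecords(records, source = "real",
                                    seed = config$seed)
    }
    .logStage(v, "group comparisons")
    comparisons <- summarizeComparisons(cohort)
    .logStage(v, "ROC analysis")
    diagnostics <- diagnosticTable(cohort,
                                   combined = config$features)
    meta <- if (config$mode == "simulate")
        .simulateMetadata(cohort, config$seed)
    else cohortTable(cohort)[, c("subject", "grade")]
    clinical <- if ("age" %in% names(meta))
        clinicalSummary(meta, categories = intersect("sex", names(meta)))
    else NULL
    .logStage(v, "writing outputs to ", config$outputDir)
    manifest <- writeOutputs(config$outputDir, maps = maps,
                             cohort = cohort, comparisons = comparisons,
                             diagnostics = diagnostics,
                             clinical = clinical,
                             config = config[setdiff(names(config),
                                                     "fitConfig")],
                             seed = config$seed)
    list(cohort = cohort, comparisons = comparisons,
         diagnostics = diagnostics, clinical = clinical,
         manifest = manifest)
}
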