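#' Construct a MetaboSet
#'
#' @param intensities numeric matrix, features x injections; `NA` marks a
#'   missing measurement.  Row names are feature ids (conventionally carrying
#'   the ionisation-mode prefix, e.g. `"pos568"`), column names injection ids.
#' @param featureData data.frame with one row per feature and columns
#'   `ion_mode`, `mz`, `rt`.
#' @param injectionData data.frame with one row per injection and columns
#'   `injection_id`, `run_order`, `sample_type`, and where applicable
#'   `injection_volume`, `subject_age`, `subject_gender`.
#'
#' @return A validated [MetaboSet-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("pos1", "pos2"), c("i1", "i2", "i3")))
#' fd <- data.frame(ion_mode = "positive", mz = c(100.1, 200.2), rt = c(10, 20))
#' id <- data.frame(injection_id = colnames(m), run_order = 1:3,
#'                  sample_type = "sample", injection_volume = NA_real_,
#'                  subject_age = c(25, 50, 70), subject_gender = "F")
#' ms <- MetaboSet(m, fd, id)
#' @export
MetaboSet <- function(intensities, featureData, injectionData) {
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    if (is.null(rownames(intensities)) && !is.null(rownames(featureData)))
        rownames(intensities) <- rownames(featureData)
    if (nrow(intensities) != nrow(featureData))
        stop("intensity rows (", nrow(intensities), ") do not match featureData rows (",
             nrow(featureData), ")")
    if (ncol(intensities) != nrow(injectionData))
        stop("intensity columns (", ncol(intensities),
             ") do not match injectionData rows (", nrow(injectionData), ")")
    for (col in c("injection_volume", "subject_age"))
        if (is.null(injectionData[[col]])) injectionData[[col]] <- NA_real_
    if (is.null(injectionData[["subject_gender"]]))
        injectionData[["subject_gender"]] <- NA_character_
    injectionData$sample_type <- as.character(injectionData$sample_type)
    injectionData$subject_gender <- as.character(injectionData$subject_gender)
    colnames(intensities) <- injectionData$injection_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensities = intensities),
        rowData = S4Vectors::DataFrame(featureData),
        colData = S4Vectors::DataFrame(injectionData, row.names = injectionData$injection_id)
    )
    new("MetaboSet", se)
}

#' Accessors for MetaboSet
#'
#' `intensities()` returns the intensity matrix; `featureMeta()` and
#' `injectionMeta()` the per-feature and per-injection metadata as plain
#' data.frames; `sampleType()`, `runOrder()`, `subjectAge()`,
#' `subjectGender()` and `injectionVolume()` the corresponding metadata
#' vectors.  `sampleInjections()`, `qcInjections()`, `blankInjections()`
#' and `dilutionInjections()` subset a `MetaboSet` to one injection type.
#'
#' @param x a [MetaboSet-class]
#' @param ... unused
#' @name MetaboSet-accessors
NULL

#' @rdname MetaboSet-accessors
#' @export
setMethod("intensities", "MetaboSet", function(x, ...)
    SummarizedExperiment::assay(x, "intensities"))

#' @rdname MetaboSet-accessors
#' @export
setMethod("featureMeta", "MetaboSet", function(x, ...)
    as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname MetaboSet-accessors
#' @export
setMethod("injectionMeta", "MetaboSet", function(x, ...)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname MetaboSet-accessors
#' @export
setMethod("sampleType", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$sample_type)

#' @rdname MetaboSet-accessors
#' @export
setMethod("runOrder", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$run_order)

#' @rdname MetaboSet-accessors
#' @export
setMethod("subjectAge", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$subject_age)

#' @rdname MetaboSet-accessors
#' @export
setMethod("subjectGender", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$subject_gender)

#' @rdname MetaboSet-accessors
#' @export
setMethod("injectionVolume", "MetaboSet", function(x, ...)
    SummarizedExperiment::colData(x)$injection_volume)

#' @rdname MetaboSet-accessors
#' @export
sampleInjections <- function(x) x[, sampleType(x) == "sample"]

#' @rdname MetaboSet-accessors
#' @export
qcInjections <- function(x) x[, sampleType(x) == "qc"]

#' @rdname MetaboSet-accessors
#' @export
blankInjections <- function(x) x[, sampleType(x) == "blank"]

#' @rdname MetaboSet-accessors
#' @export
dilutionInjections <- function(x) x[, sampleType(x) == "dilution"]

setMethod("show", "MetaboSet", function(object) {
    st <- table(factor(sampleType(object), levels = .SAMPLE_TYPES))
    cat("MetaboSet:", nrow(object), "features x", ncol(object), "injections\n")
    cat("  injections:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
    md <- table(factor(featureMeta(object)$ion_mode,
                       levels = c("positive", "negative")))
    cat("  ion modes:", paste(sprintf("%s=%d", names(md), md), collapse = ", "), "\n")
    nmiss <- sum(is.na(intensities(object)))
    cat("  missing cells:", nmiss, "\n")
    invisible(NULL)
})

#' @rdname FilterReport-accessors
#' @export
setMethod("removedFeatures", "FilterReport", function(x, ...) x@removedIds)

#' Accessors for FilterReport
#' @param x a [FilterReport-class]
#' @param ... unused
#' @name FilterReport-accessors
NULL

setMethod("show", "FilterReport", function(object) {
    cat(sprintf("FilterReport [%s]: %d -> %d features (%d removed)\n",
                object@stage, object@nIn, object@nOut, length(object@removedIds)))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = "; "), "\n")
    invisible(NULL)
})

setMethod("show", "BorutaResult", function(object) {
    d <- table(object@decision)
    cat(sprintf("BorutaResult (target = %s): %d iterations\n",
                object@target, object@nIterations))
    cat(sprintf("  confirmed=%d tentative=%d rejected=%d\n",
                d[["confirmed"]], d[["tentative"]], d[["rejected"]]))
    if (!is.na(object@validationR2))
        cat(sprintf("  validation R2 (regression tree) = %.3f\n", object@validationR2))
    if (!is.na(object@oobR2))
        cat(sprintf("  out-of-bag R2 (random forest)   = %.3f\n", object@oobR2))
    invisible(NULL)
})

setMethod("show", "OrdinationResult", function(object) {
    cat(sprintf("OrdinationResult (%s): %d sites\n",
                object@metric, nrow(object@siteScores)))
    cat(sprintf("  total inertia = %.4f, constrained = %.2f%%\n",
                object@totalInertia,
                100 * object@constrainedFraction[["total"]]))
    if (length(object@permutationP) && !all(is.na(object@permutationP)))
        cat("  permutation p:",
            paste(sprintf("%s=%.4g", names(object@permutationP), object@permutationP),
                  collapse = ", "), "\n")
    invisible(NULL)
})

#' Accessors for BorutaResult
#'
#' `decisions()` returns the named per-feature decision factor;
#' `confirmedFeatures()` the ids of confirmed features.
#'
#' @param x a [BorutaResult-class]
#' @param ... unused
#' @name BorutaResult-accessors
NULL

#' @rdname BorutaResult-accessors
#' @export
setMethod("decisions", "BorutaResult", function(x, ...) x@decision)

#' @rdname BorutaResult-accessors
#' @export
setMethod("confirmedFeatures", "BorutaResult", function(x, ...)
    names(x@decision)[x@decision == "confirmed"])

#' Accessors for OrdinationResult
#'
#' `constrainedFraction()` returns the named vector of inertia fractions
#' (one per constraint plus `"total"`); `siteScores()` the site scores on
#' the constrained axes; `eigenvalues()` a list with the constrained and
#' residual eigenvalues (negative residual eigenvalues retained).
#'
#' @param x an [OrdinationResult-class]
#' @param ... unused
#' @name OrdinationResult-accessors
NULL

#' @rdname OrdinationResult-accessors
#' @export
setMethod("constrainedFraction", "OrdinationResult", function(x, ...)
    x@constrainedFraction)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("siteScores", "OrdinationResult", function(x, ...) x@siteScores)

#' @rdname OrdinationResult-accessors
#' @export
setMethod("eigenvalues", "OrdinationResult", function(x, ...)
    list(constrained = x@constrainedEig, residual = x@residualEig))
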