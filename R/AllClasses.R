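#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SAMPLE_TYPES <- c("sample", "qc", "blank", "dilution")

#' MetaboSet: an LC-MS feature table with injection metadata
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' features-by-injections intensity matrix from an untargeted metabolomics
#' experiment.  Rows are metabolite features (an m/z, retention-time pair per
#' ionisation mode), columns are injections of any of the four acquisition
#' types used by pooled-QC study designs: study samples, pooled-QC
#' injections, solvent blanks, and a QC dilution ladder.
#'
#' Required `rowData` columns: `ion_mode` (`"positive"`/`"negative"`),
#' `mz` (Da, > 0), `rt` (seconds, >= 0).  Required `colData` columns:
#' `injection_id`, `run_order` (unique 1-based acquisition position),
#' `sample_type` (one of `sample`, `qc`, `blank`, `dilution`),
#' `injection_volume` (microlitres; non-`NA` iff `sample_type == "dilution"`),
#' `subject_age` (years) and `subject_gender` (`"M"`/`"F"`), both non-`NA`
#' iff `sample_type == "sample"`.
#'
#' Intensities are non-negative where observed; missing cells are `NA` and
#' are never silently zero-filled.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [MetaboSet()] for the constructor, [readFeatureTable()] for I/O.
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

.validMetaboSet <- function(object) {
    msg <- character()
    if (!"intensities" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensities' is required")
    rd <- SummarizedExperiment::rowData(object)
    cd <- SummarizedExperiment::colData(object)
    need_rd <- c("ion_mode", "mz", "rt")
    need_cd <- c("injection_id", "run_order", "sample_type",
                 "injection_volume", "subject_age", "subject_gender")
    if (!all(need_rd %in% colnames(rd)))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(setdiff(need_rd, colnames(rd)), collapse = ", ")))
    if (!all(need_cd %in% colnames(cd)))
        msg <- c(msg, paste0("colData must contain: ",
                             paste(setdiff(need_cd, colnames(cd)), collapse = ", ")))
    if (length(msg))
        return(msg)
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, paste0("duplicated feature_id: ",
                             paste(unique(rownames(object)[duplicated(rownames(object))]),
                                   collapse = ", ")))
    if (anyDuplicated(cd$injection_id))
        msg <- c(msg, paste0("duplicated injection_id: ",
                             paste(unique(cd$injection_id[duplicated(cd$injection_id)]),
                                   collapse = ", ")))
    if (anyDuplicated(cd$run_order))
        msg <- c(msg, "run_order values must be unique within a table")
    if (!all(cd$sample_type %in% .SAMPLE_TYPES))
        msg <- c(msg, paste0("sample_type must be one of: ",
                             paste(.SAMPLE_TYPES, collapse = ", ")))
    if (!all(rd$ion_mode %in% c("positive", "negative")))
        msg <- c(msg, "ion_mode must be 'positive' or 'negative'")
    if (any(!is.na(rd$mz) & rd$mz <= 0))
        msg <- c(msg, "mz must be positive")
    if (any(!is.na(rd$rt) & rd$rt < 0))
        msg <- c(msg, "rt must be non-negative")
    x <- SummarizedExperiment::assay(object, "intensities")
    if (any(x < 0, na.rm = TRUE)) {
        bad <- which(x < 0, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("negative intensity at feature '%s', injection '%s'",
                              rownames(object)[bad[1L]], colnames(object)[bad[2L]]))
    }
    is_dil <- cd$sample_type == "dilution"
    if (any(is_dil & is.na(cd$injection_volume)))
        msg <- c(msg, "dilution injections must carry injection_volume")
    is_smp <- cd$sample_type == "sample"
    if (any(is_smp & (is.na(cd$subject_age) | is.na(cd$subject_gender))))
        msg <- c(msg, "sample injections must carry subject_age and subject_gender")
    if (any(!is.na(cd$subject_gender) & !cd$subject_gender %in% c("M", "F")))
        msg <- c(msg, "subject_gender must be 'M' or 'F'")
    if (length(msg)) msg else TRUE
}

setValidity("MetaboSet", .validMetaboSet)

#' Pipeline configuration
#'
#' Holds every tunable constant of the analysis chain.  Defaults are the
#' published values of the workflow this package implements: blank
#' contaminants flagged above 1% of the maximum sample intensity, dilution
#' Pearson filter at p < 0.05, LOESS span 0.2, QC CV threshold 20%,
#' presence rule 75%, Boruta with Bonferroni adjustment and up to 1000
#' iterations over 500-tree forests, 999 permutations for ordination tests,
#' Fisher enrichment at the conservative alpha 0.005, and a 10 ppm mass
#' tolerance for library matching.
#'
#' @seealso [pipelineConfig()]
#' @export
setClass("PipelineConfig",
    representation(
        blank_fraction = "numeric",
        dilution_alpha = "numeric",
        loess_span = "numeric",
        cv_threshold = "numeric",
        presence_fraction = "numeric",
        boruta_max_runs = "integer",
        boruta_bonferroni = "logical",
        n_trees = "integer",
        n_permutations = "integer",
        fisher_alpha = "numeric",
        ppm_tolerance = "numeric",
        rng_seed = "integer"
    )
)

.validPipelineConfig <- function(object) {
    msg <- character()
    fr <- c(blank_fraction = object@blank_fraction,
            dilution_alpha = object@dilution_alpha,
            loess_span = object@loess_span,
            cv_threshold = object@cv_threshold,
            presence_fraction = object@presence_fraction,
            fisher_alpha = object@fisher_alpha)
    bad <- names(fr)[fr <= 0 | fr >= 1]
    if (length(bad))
        msg <- c(msg, paste0("fractions must lie in (0,1): ", paste(bad, collapse = ", ")))
    cnt <- c(boruta_max_runs = object@boruta_max_runs,
             n_trees = object@n_trees, n_permutations = object@n_permutations)
    if (any(cnt < 1L))
        msg <- c(msg, "counts must be positive")
    if (object@ppm_tolerance <= 0)
        msg <- c(msg, "ppm_tolerance must be positive")
    if (length(msg)) msg else TRUE
}

setValidity("PipelineConfig", .validPipelineConfig)

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic CSF aging cohort: 41 subjects aged 20-74,
#' 1169 positive-mode plus 672 negative-mode features, 69 planted
#' age-linear features of which 5 decrease with age, 41 gender-associated
#' features, solvent-blank contaminants, pooled-QC injections carrying a
#' smooth multiplicative run-order drift, and a twofold dilution ladder
#' from 0.5 to 32 microlitres.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
    representation(
        n_subjects = "integer",
        age_range = "numeric",
        n_features_pos = "integer",
        n_features_neg = "integer",
        n_age_features = "integer",
        n_decreasing = "integer",
        n_gender_features = "integer",
        n_contaminants = "integer",
        qc_every = "integer",
        n_blanks = "integer",
        dilution_volumes = "numeric",
        drift_amplitude = "numeric",
        noise_cv = "numeric",
        effect_r2 = "numeric",
        missing_rate = "numeric",
        n_classes = "integer",
        n_enriched_classes = "integer",
        class_odds_ratio = "numeric",
        rng_seed = "integer"
    )
)

.validCohortConfig <- function(object) {
    msg <- character()
    ntot <- object@n_features_pos + object@n_features_neg
    if (object@n_age_features + object@n_gender_features +
        object@n_contaminants > ntot)
        msg <- c(msg, "more planted features than features in total")
    if (object@n_decreasing > object@n_age_features)
        msg <- c(msg, "n_decreasing exceeds n_age_features")
    if (length(object@age_range) != 2L || diff(object@age_range) <= 0)
        msg <- c(msg, "age_range must be an increasing pair of years")
    v <- object@dilution_volumes
    if (length(v) < 3L || any(abs(v[-1L] / v[-length(v)] - 2) > 1e-8))
        msg <- c(msg, "dilution_volumes must be a strictly twofold ladder")
    if (object@noise_cv < 0 || object@drift_amplitude < 0)
        msg <- c(msg, "noise_cv and drift_amplitude must be non-negative")
    if (object@effect_r2 < 0 || object@effect_r2 >= 1)
        msg <- c(msg, "effect_r2 must lie in [0,1)")
    if (object@missing_rate < 0 || object@missing_rate >= 1)
        msg <- c(msg, "missing_rate must lie in [0,1)")
    if (object@class_odds_ratio <= 0)
        msg <- c(msg, "class_odds_ratio must be positive")
    if (length(msg)) msg else TRUE
}

setValidity("CohortConfig", .validCohortConfig)

#' Per-stage quality-control filter report
#'
#' Records, for one filtering stage, the incoming and outgoing feature
#' counts, the identities of removed features, per-feature diagnostics
#' (e.g. median blank ratio, dilution Pearson r and p, QC CV before/after
#' correction) and any stage flags (e.g. the median-factor LOESS fallback).
#'
#' @export
setClass("FilterReport",
    representation(
        stage = "character",
        nIn = "integer",
        nOut = "integer",
        removedIds = "character",
        diagnostics = "data.frame",
        flags = "character"
    )
)

setValidity("FilterReport", function(object) {
    if (object@nOut != object@nIn - length(object@removedIds))
        "nOut must equal nIn - length(removedIds)"
    else TRUE
})

#' Boruta shadow-feature selection result
#'
#' Per-feature decisions (`confirmed`/`tentative`/`rejected`), hit counts
#' against the best shadow feature, the per-iteration importance Z-score
#' history, and the validation statistics of the final model restricted to
#' confirmed features.
#'
#' @export
setClass("BorutaResult",
    representation(
        decision = "factor",
        hitCount = "integer",
        nIterations = "integer",
        zHistory = "matrix",
        target = "character",
        validationR2 = "numeric",
        oobR2 = "numeric",
        runInfo = "list"
    )
)

setValidity("BorutaResult", function(object) {
    msg <- character()
    if (!all(levels(object@decision) == c("confirmed", "tentative", "rejected")))
        msg <- c(msg, "decision levels must be confirmed/tentative/rejected")
    if (any(object@hitCount > object@nIterations))
        msg <- c(msg, "hitCount cannot exceed nIterations")
    if (length(msg)) msg else TRUE
})

#' Distance-based redundancy analysis result
#'
#' Constrained ordination of a dissimilarity matrix on covariates by the
#' McArdle-Anderson formulation.  Holds the constrained and residual
#' eigenvalues (negative residual eigenvalues of non-Euclidean
#' dissimilarities are retained in the total inertia), site scores on the
#' constrained axes, the fraction of total inertia explained by the
#' constraints, the pseudo-F statistic, and permutation p-values when
#' computed.  The Gower-centred matrix and constraint design are kept so
#' permutation tests and post-hoc fits can be run on the object.
#'
#' @export
setClass("OrdinationResult",
    representation(
        constrainedEig = "numeric",
        residualEig = "numeric",
        siteScores = "matrix",
        constrainedFraction = "numeric",
        totalInertia = "numeric",
        pseudoF = "numeric",
        permutationP = "numeric",
        G = "matrix",
        constraints = "matrix",
        metric = "character"
    )
)

setValidity("OrdinationResult", function(object) {
    msg <- character()
    cf <- object@constrainedFraction
    if (any(cf < -1e-12 | cf > 1 + 1e-12))
        msg <- c(msg, "constrainedFraction must lie in [0,1]")
    p <- object@permutationP
    if (length(p) && any(p <= 0 | p > 1, na.rm = TRUE))
        msg <- c(msg, "permutation p must lie in (0,1]")
    if (length(msg)) msg else TRUE
})
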