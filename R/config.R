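#' Create a pipeline configuration
#'
#' All arguments default to the published workflow constants; see
#' [PipelineConfig-class] for their meaning.
#'
#' @param blank_fraction blank filter threshold as a fraction of the maximum
#'   sample intensity (default 0.01, i.e. 1%).
#' @param dilution_alpha two-sided p-value cut-off of the dilution-series
#'   Pearson filter (default 0.05).
#' @param loess_span LOESS span for run-order drift correction (default 0.2).
#' @param cv_threshold QC coefficient-of-variation retention threshold
#'   (default 0.20; strict `<`).
#' @param presence_fraction minimum fraction of study samples in which a
#'   feature must be observed (default 0.75).
#' @param boruta_max_runs maximum Boruta iterations (default 1000).
#' @param boruta_bonferroni Bonferroni-adjust the per-feature binomial tests
#'   across undecided features (default `TRUE`).
#' @param n_trees trees per random forest (default 500).
#' @param n_permutations permutations for ordination tests (default 999).
#' @param fisher_alpha enrichment alpha (default 0.005, conservative).
#' @param ppm_tolerance library-match mass tolerance in ppm (default 10).
#' @param rng_seed seed used by all randomised stages (default 1).
#'
#' @return a validated [PipelineConfig-class]
#' @examples
#' cfg <- pipelineConfig(n_permutations = 199, rng_seed = 7)
#' @export
pipelineConfig <- function(blank_fraction = 0.01,
                           dilution_alpha = 0.05,
                           loess_span = 0.2,
                           cv_threshold = 0.20,
                           presence_fraction = 0.75,
                           boruta_max_runs = 1000L,
                           boruta_bonferroni = TRUE,
                           n_trees = 500L,
                           n_permutations = 999L,
                           fisher_alpha = 0.005,
                           ppm_tolerance = 10,
                           rng_seed = 1L) {
    new("PipelineConfig",
        blank_fraction = blank_fraction,
        dilution_alpha = dilution_alpha,
        loess_span = loess_span,
        cv_threshold = cv_threshold,
        presence_fraction = presence_fraction,
        boruta_max_runs = as.integer(boruta_max_runs),
        boruta_bonferroni = isTRUE(boruta_bonferroni),
        n_trees = as.integer(n_trees),
        n_permutations = as.integer(n_permutations),
        fisher_alpha = fisher_alpha,
        ppm_tolerance = ppm_tolerance,
        rng_seed = as.integer(rng_seed))
}

#' Create a synthetic cohort configuration
#'
#' Defaults mirror the study design the package emulates: 41 subjects aged
#' 20-74; 1169 positive- and 672 negative-mode features; 69 age-linear
#' features, 5 of them decreasing; 41 gender features; 50 blank-only
#' contaminants; a pooled QC every 8 injections; 5 solvent blanks; a
#' twofold dilution ladder 0.5-32 uL; 20% multiplicative run-order drift;
#' 5% lognormal technical noise; age features scaled to explain 40% of
#' their variance; 5% completely-at-random missingness; a catalogue of 190
#' chemical classes with 5 of them enriched among age features at odds
#' ratio 20.
#'
#' @param n_subjects,age_range cohort size and age span (years).
#' @param n_features_pos,n_features_neg feature counts per ionisation mode.
#' @param n_age_features,n_decreasing planted age-linear features and how
#'   many of them decrease with age.
#' @param n_gender_features planted gender-associated features (disjoint
#'   from the age set).
#' @param n_contaminants planted blank-only contaminant features.
#' @param qc_every pooled-QC injection every this many injections.
#' @param n_blanks number of solvent blank injections.
#' @param dilution_volumes twofold dilution ladder in microlitres.
#' @param drift_amplitude peak relative amplitude of the smooth
#'   multiplicative run-order drift.
#' @param noise_cv lognormal technical coefficient of variation.
#' @param effect_r2 target fraction of an age feature's sample variance
#'   explained by age.
#' @param missing_rate completely-at-random missingness among sample cells.
#' @param n_classes,n_enriched_classes,class_odds_ratio chemical-class
#'   catalogue size, number of classes planted as enriched among age
#'   features, and their enrichment odds ratio.
#' @param rng_seed generator seed.
#'
#' @return a validated [CohortConfig-class]
#' @examples
#' cc <- cohortConfig(n_features_pos = 60, n_features_neg = 40,
#'                    n_age_features = 10, n_gender_features = 5,
#'                    n_contaminants = 5)
#' @export
cohortConfig <- function(n_subjects = 41L,
                         age_range = c(20, 74),
                         n_features_pos = 1169L,
                         n_features_neg = 672L,
                         n_age_features = 69L,
                         n_decreasing = 5L,
                         n_gender_features = 41L,
                         n_contaminants = 50L,
                         qc_every = 8L,
                         n_blanks = 5L,
                         dilution_volumes = c(0.5, 1, 2, 4, 8, 16, 32),
                         drift_amplitude = 0.2,
                         noise_cv = 0.05,
                         effect_r2 = 0.4,
                         missing_rate = 0.05,
                         n_classes = 190L,
                         n_enriched_classes = 5L,
                         class_odds_ratio = 20,
                         rng_seed = 1L) {
    new("CohortConfig",
        n_subjects = as.integer(n_subjects),
        age_range = as.numeric(age_range),
        n_features_pos = as.integer(n_features_pos),
        n_features_neg = as.integer(n_features_neg),
        n_age_features = as.integer(n_age_features),
        n_decreasing = as.integer(n_decreasing),
        n_gender_features = as.integer(n_gender_features),
        n_contaminants = as.integer(n_contaminants),
        qc_every = as.integer(qc_every),
        n_blanks = as.integer(n_blanks),
        dilution_volumes = as.numeric(dilution_volumes),
        drift_amplitude = drift_amplitude,
        noise_cv = noise_cv,
        effect_r2 = effect_r2,
        missing_rate = missing_rate,
        n_classes = as.integer(n_classes),
        n_enriched_classes = as.integer(n_enriched_classes),
        class_odds_ratio = class_odds_ratio,
        rng_seed = as.integer(rng_seed))
}

#' Write a run manifest
#'
#' Serialises a configuration (plus the package version and a timestamp) as
#' JSON next to pipeline outputs, so a run can be reproduced from its seed
#' and constants alone.
#'
#' @param config a [PipelineConfig-class] or [CohortConfig-class]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
writeRunManifest <- function(config, path) {
    sl <- methods::slotNames(class(config))
    vals <- lapply(sl, function(s) methods::slot(config, s))
    names(vals) <- sl
    manifest <- list(
        class = as.character(class(config)),
        package_version = as.character(utils::packageVersion("metaboDrift")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = vals)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
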