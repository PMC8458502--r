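#' Generate a synthetic CSF aging cohort
#'
#' Builds a feature table with the statistical structure the downstream
#' analysis assumes, plus the ground truth needed for recovery tests:
#'
#' * per-feature lognormal baseline intensities;
#' * planted age-linear features whose sample intensity is a linear
#'   function of age on the raw scale, with the slope chosen so that age
#'   explains `effect_r2` of the feature's variance at the configured
#'   technical noise (with `noise_cv = 0` the column is an exact linear
#'   function of age);
#' * planted gender features (disjoint from the age set) and blank-only
#'   contaminant features (flat across all injection types);
#' * pooled-QC injections every `qc_every` injections, solvent blanks, and
#'   a twofold dilution ladder whose non-contaminant intensities scale
#'   linearly with injected volume (reference sample volume 10 uL);
#' * a smooth multiplicative run-order drift (low-order trend plus a slow
#'   sinusoid, peak relative amplitude `drift_amplitude`) applied to every
#'   injection;
#' * multiplicative lognormal technical noise with coefficient of
#'   variation `noise_cv`, and completely-at-random missingness at
#'   `missing_rate` among sample cells.
#'
#' Sample injection order is randomised blocked on age tertiles (the
#' tertiles are interleaved), emulating an acquisition sequence randomised
#' under an age constraint.  The generator is deterministic for a fixed
#' `rng_seed`.
#'
#' @param config a [CohortConfig-class]
#' @return a list with elements `cohort` (a [MetaboSet-class]) and `truth`
#'   (a list with `age_features` -- data.frame of `feature_id`, `direction`,
#'   `beta` --, `gender_features`, `contaminant_ids`, `drift_curve` (one
#'   multiplicative factor per run order), `ages`, `genders`)
#' @examples
#' sim <- generateCohort(cohortConfig(n_features_pos = 40, n_features_neg = 20,
#'                                    n_age_features = 5, n_gender_features = 3,
#'                                    n_contaminants = 3))
#' sim$cohort
#' @export
generateCohort <- function(config = cohortConfig()) {
    stopifnot(methods::is(config, "CohortConfig"))
    methods::validObject(config)
    set.seed(config@rng_seed)

    n_pos <- config@n_features_pos
    n_neg <- config@n_features_neg
    n_feat <- n_pos + n_neg
    feature_id <- c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg)))
    ion_mode <- rep(c("positive", "negative"), c(n_pos, n_neg))
    mz <- stats::runif(n_feat, 60, 800)
    rt <- stats::runif(n_feat, 30, 700)
    baseline <- 10 ^ stats::rnorm(n_feat, mean = 5, sd = 0.4)

    planted <- sample.int(n_feat, config@n_age_features +
                              config@n_gender_features + config@n_contaminants)
    idx_age <- planted[seq_len(config@n_age_features)]
    idx_gender <- planted[config@n_age_features + seq_len(config@n_gender_features)]
    idx_cont <- planted[config@n_age_features + config@n_gender_features +
                            seq_len(config@n_contaminants)]
    sign_age <- rep(1, config@n_age_features)
    if (config@n_decreasing > 0L)
        sign_age[sample.int(config@n_age_features, config@n_decreasing)] <- -1

    # Subjects: ages spread over the range (jittered grid), genders balanced.
    n_s <- config@n_subjects
    ages <- seq(config@age_range[1L], config@age_range[2L], length.out = n_s)
    ages <- round(pmin(pmax(ages + stats::rnorm(n_s, 0, 1.5),
                            config@age_range[1L]), config@age_range[2L]))
    genders <- sample(rep_len(c("M", "F"), n_s))
    subject_id <- sprintf("S%02d_%s", seq_len(n_s), genders)

    # Age-constrained randomisation: interleave age tertiles.
    tert <- cut(rank(ages, ties.method = "first"), 3L, labels = FALSE)
    pools <- lapply(1:3, function(t) sample(which(tert == t)))
    order_s <- integer(0)
    while (any(lengths(pools) > 0L)) {
        for (t in sample(1:3)) {
            if (length(pools[[t]])) {
                order_s <- c(order_s, pools[[t]][1L])
                pools[[t]] <- pools[[t]][-1L]
            }
        }
    }

    # Acquisition schedule: lead-in QC, a QC every qc_every injections,
    # blanks following evenly spaced QCs, dilution ladder at the end.
    sched <- data.frame(kind = "qc", subject = NA_integer_,
                        volume = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_along(order_s)) {
        sched <- rbind(sched, data.frame(kind = "sample", subject = order_s[i],
                                         volume = NA_real_))
        if (i %% config@qc_every == 0L || i == length(order_s))
            sched <- rbind(sched, data.frame(kind = "qc", subject = NA_integer_,
                                             volume = NA_real_))
    }
    qc_pos <- which(sched$kind == "qc")
    blank_after <- qc_pos[unique(round(seq(1L, length(qc_pos),
                                           length.out = min(config@n_blanks,
                                                            length(qc_pos)))))]
    sched$blank_after <- seq_len(nrow(sched)) %in% blank_after
    rows <- list()
    for (i in seq_len(nrow(sched))) {
        rows[[length(rows) + 1L]] <- sched[i, c("kind", "subject", "volume")]
        if (sched$blank_after[i])
            rows[[length(rows) + 1L]] <- data.frame(kind = "blank",
                                                    subject = NA_integer_,
                                                    volume = NA_real_)
    }
    sched <- do.call(rbind, rows)
    for (v in config@dilution_volumes)
        sched <- rbind(sched, data.frame(kind = "dilution",
                                         subject = NA_integer_, volume = v))
    n_inj <- nrow(sched)
    run_order <- seq_len(n_inj)

    injection_id <- character(n_inj)
    counts <- c(qc = 0L, blank = 0L, dilution = 0L)
    for (i in seq_len(n_inj)) {
        k <- sched$kind[i]
        if (k == "sample") {
            injection_id[i] <- subject_id[sched$subject[i]]
        } else {
            counts[k] <- counts[k] + 1L
            injection_id[i] <- sprintf("%s%02d", toupper(substr(k, 1L, 2L)), counts[k])
        }
    }

    # Smooth multiplicative drift, peak relative amplitude drift_amplitude.
    u <- (run_order - 1) / max(1L, n_inj - 1L)
    phase <- stats::runif(1, 0, 2 * pi)
    raw <- sin(2 * pi * 1.3 * u + phase) + 0.8 * (u - 0.5)
    drift <- 1 + config@drift_amplitude * raw / max(abs(raw))

    # Effect sizes: slope beta (relative intensity per unit of scaled age)
    # solving effect_r2 = var(signal) / (var(signal) + var(noise)).
    u_age <- (ages - config@age_range[1L]) / diff(config@age_range)
    if (config@noise_cv > 0) {
        k <- sqrt(config@effect_r2 / (1 - config@effect_r2))
        den <- stats::sd(u_age) - k * config@noise_cv * mean(u_age)
        beta <- if (den > 0) min(k * config@noise_cv / den, 0.8) else 0.8
        kg <- k
        gamma <- min(kg * config@noise_cv / 0.5, 0.8)
    } else {
        beta <- 0.5
        gamma <- 0.5
    }

    is_cont <- seq_len(n_feat) %in% idx_cont
    age_fac <- matrix(1, n_feat, n_s)
    for (j in seq_along(idx_age)) {
        f <- idx_age[j]
        age_fac[f, ] <- if (sign_age[j] > 0) 1 + beta * u_age else 1 + beta * (1 - u_age)
    }
    gender_fac <- matrix(1, n_feat, n_s)
    gender_fac[idx_gender, ] <- rep(ifelse(genders == "M", 1 + gamma, 1),
                                    each = length(idx_gender))
    subj_fac <- age_fac * gender_fac
    pool_fac <- rowMeans(subj_fac)

    signal <- matrix(0, n_feat, n_inj,
                     dimnames = list(feature_id, injection_id))
    for (i in seq_len(n_inj)) {
        signal[, i] <- switch(sched$kind[i],
            sample = ifelse(is_cont, baseline,
                            baseline * subj_fac[, sched$subject[i]]),
            qc = ifelse(is_cont, baseline, baseline * pool_fac),
            blank = ifelse(is_cont, baseline, baseline * 1e-3),
            dilution = ifelse(is_cont, baseline,
                              baseline * pool_fac * sched$volume[i] / 10))
    }
    signal <- sweep(signal, 2L, drift, `*`)
    if (config@noise_cv > 0) {
        sigma <- sqrt(log(1 + config@noise_cv^2))
        noise <- matrix(exp(stats::rnorm(n_feat * n_inj, -sigma^2 / 2, sigma)),
                        n_feat, n_inj)
        signal <- signal * noise
    }
    if (config@missing_rate > 0) {
        smp_cols <- which(sched$kind == "sample")
        miss <- matrix(stats::runif(n_feat * length(smp_cols)) < config@missing_rate,
                       n_feat, length(smp_cols))
        signal[, smp_cols][miss] <- NA_real_
    }

    fd <- data.frame(ion_mode = ion_mode, mz = mz, rt = rt,
                     row.names = feature_id)
    id <- data.frame(injection_id = injection_id,
                     run_order = run_order,
                     sample_type = sched$kind,
                     injection_volume = sched$volume,
                     subject_age = ifelse(sched$kind == "sample",
                                          ages[sched$subject], NA_real_),
                     subject_gender = ifelse(sched$kind == "sample",
                                             genders[sched$subject], NA_character_),
                     stringsAsFactors = FALSE)
    cohort <- MetaboSet(signal, fd, id)
    truth <- list(
        age_features = data.frame(
            feature_id = feature_id[idx_age],
            direction = ifelse(sign_age > 0, "increasing", "decreasing"),
            beta = beta * sign_age, stringsAsFactors = FALSE),
        gender_features = feature_id[idx_gender],
        contaminant_ids = feature_id[idx_cont],
        all_feature_ids = feature_id,
        drift_curve = drift,
        ages = ages, genders = genders,
        config = config)
    list(cohort = cohort, truth = truth)
}

# Superclass names used to build the synthetic chemical-class catalogue.
.CLASS_SUPERCLASSES <- c(
    "Organic acids and derivatives",
    "Organoheterocyclic compounds",
    "Organic oxygen compounds",
    "Benzenoids",
    "Lipids and lipid-like molecules",
    "Phenylpropanoids and polyketides",
    "Nucleosides, nucleotides, and analogues",
    "Organic nitrogen compounds",
    "Alkaloids and derivatives",
    "Organosulfur compounds")

#' Synthetic chemical-class catalogue
#'
#' Hierarchical leaf-class paths of the form
#' `"Organic compounds/<superclass>/<class>"`, distributed over ten
#' superclass branches.
#'
#' @param n_classes number of leaf classes (default 190)
#' @return character vector of leaf paths
#' @export
classCatalogue <- function(n_classes = 190L) {
    sup <- rep_len(.CLASS_SUPERCLASSES, n_classes)
    idx <- stats::ave(seq_len(n_classes), sup, FUN = seq_along)
    sort(paste0("Organic compounds/", sup, "/", sub("^(\\w+).*", "\\1", sup),
                " class ", sprintf("%03d", idx)))
}

#' Assign chemical classes to cohort features
#'
#' Every feature receives a leaf path from the class catalogue.  Background
#' features draw uniformly; planted age features draw with the designated
#' enriched classes up-weighted by `class_odds_ratio`, so a downstream
#' selected-vs-background class enrichment can recover the planted classes.
#'
#' @param truth ground truth from [generateCohort()]
#' @param config the [CohortConfig-class] used for the cohort (supplies the
#'   catalogue size, number of enriched classes, odds ratio and seed)
#' @return data.frame with columns `feature_id`, `class_path`; the planted
#'   enriched class paths are attached as `attr(, "enriched_classes")`
#' @export
generateSpectralClasses <- function(truth, config = truth$config) {
    stopifnot(is.list(truth), !is.null(truth$age_features))
    if (config@class_odds_ratio <= 0)
        stop("class odds ratio must be positive")
    set.seed(config@rng_seed + 1L)
    catalogue <- classCatalogue(config@n_classes)
    enriched <- sample(catalogue, config@n_enriched_classes)
    all_ids <- truth$all_feature_ids
    if (is.null(all_ids))
        all_ids <- c(paste0("pos", seq_len(config@n_features_pos)),
                     paste0("neg", seq_len(config@n_features_neg)))
    is_age <- all_ids %in% truth$age_features$feature_id
    w_bg <- rep(1, length(catalogue))
    # convert the target per-class odds ratio into multinomial weights:
    # an enriched class should have membership odds OR times the background
    # odds, after normalisation across the whole catalogue
    n_cl <- length(catalogue)
    k <- config@n_enriched_classes
    p_bg <- 1 / n_cl
    odds_t <- config@class_odds_ratio * p_bg / (1 - p_bg)
    p_e <- odds_t / (1 + odds_t)
    w_e <- if (k * p_e < 1) p_e * (n_cl - k) / (1 - k * p_e) else config@class_odds_ratio
    w_age <- ifelse(catalogue %in% enriched, w_e, 1)
    cls <- character(length(all_ids))
    cls[!is_age] <- sample(catalogue, sum(!is_age), replace = TRUE, prob = w_bg)
    cls[is_age] <- sample(catalogue, sum(is_age), replace = TRUE, prob = w_age)
    out <- data.frame(feature_id = all_ids, class_path = cls,
                      stringsAsFactors = FALSE)
    attr(out, "enriched_classes") <- sort(enriched)
    out
}

#' Generate a synthetic multi-source ontology-path table
#'
#' Emulates ontology metadata gathered from several public sources per
#' compound: retained informative branches (biological locations, pathways,
#' disorders), deliberate duplicate case variants of the same term (e.g.
#' `"Biological location/Blood"` and `"biological location/blood"`), and
#' branches on the default removal list (e.g. `"Disposition/Source/..."`),
#' so that pruning and normalisation can be exercised.  The first compound
#' always carries a `Disposition/Source` path and a case-variant duplicate.
#'
#' @param compound_ids character vector of compound identifiers; an empty
#'   vector yields an empty table
#' @param seed RNG seed
#' @return data.frame with columns `compound_id`, `source`, `path`
#' @export
generateOntologyFixture <- function(compound_ids, seed = 1L) {
    if (length(compound_ids) == 0L)
        return(data.frame(compound_id = character(), source = character(),
                          path = character(), stringsAsFactors = FALSE))
    set.seed(seed)
    retained <- c("Biological location/Blood",
                  "Biological location/Urine",
                  "Biological location/Faeces",
                  "Biological location/Cerebrospinal fluid",
                  "Pathways/Tryptophan metabolism",
                  "Pathways/Purine metabolism",
                  "Pathways/Caffeine metabolism",
                  "Pathways/Nicotinamide metabolism",
                  "Disorders and diseases/Neurodegeneration",
                  "Disorders and diseases/Colorectal cancer",
                  "Role/Biological role/Waste product",
                  "Role/Biological role/Neurotransmitter")
    removable <- c("Disposition/Source/Endogenous",
                   "Disposition/Source/Food",
                   "Disposition/Route of exposure/Oral",
                   "Process/Biological process/Metabolic process",
                   "Taxonomy/Organic compounds",
                   "Target-based classification of drugs/Enzyme inhibitors")
    rows <- lapply(seq_along(compound_ids), function(i) {
        id <- compound_ids[i]
        keep <- sample(retained, sample(2:4, 1L))
        extra <- if (i == 1L) c("Disposition/Source/Endogenous",
                                tolower(keep[1L]))
                 else {
                     e <- character(0)
                     if (stats::runif(1) < 0.5) e <- c(e, sample(removable, 1L))
                     if (stats::runif(1) < 0.3) e <- c(e, tolower(keep[1L]))
                     e
                 }
        p <- c(keep, extra)
        data.frame(compound_id = id,
                   source = sample(c("hmdb", "chebi", "kegg"), length(p),
                                   replace = TRUE),
                   path = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
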