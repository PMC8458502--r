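test_that("generator is deterministic and produces the configured design", {
    cfg <- smallCohortConfig(11)
    sim1 <- generateCohort(cfg)
    sim2 <- generateCohort(cfg)
    expect_identical(intensities(sim1$cohort), intensities(sim2$cohort))
    expect_identical(sim1$truth$age_features, sim2$truth$age_features)

    st <- table(sampleType(sim1$cohort))
    expect_identical(unname(st[["sample"]]), 41L)
    expect_identical(unname(st[["dilution"]]), 7L)
    expect_identical(unname(st[["blank"]]), 5L)
    expect_identical(nrow(sim1$cohort), 200L)

    # planted sets are disjoint
    tr <- sim1$truth
    expect_length(intersect(tr$age_features$feature_id, tr$gender_features), 0)
    expect_length(intersect(tr$age_features$feature_id, tr$contaminant_ids), 0)
    expect_length(intersect(tr$gender_features, tr$contaminant_ids), 0)
})

test_that("full-scale default design matches the study dimensions", {
    sim <- generateCohort(cohortConfig(rng_seed = 2))
    expect_identical(nrow(sim$cohort), 1841L)
    expect_identical(sum(sampleType(sim$cohort) == "sample"), 41L)
    md <- table(featureMeta(sim$cohort)$ion_mode)
    expect_identical(unname(md[["positive"]]), 1169L)
    expect_identical(unname(md[["negative"]]), 672L)
    expect_identical(nrow(sim$truth$age_features), 69L)
    expect_identical(sum(sim$truth$age_features$direction == "decreasing"), 5L)
    ages <- subjectAge(sampleInjections(sim$cohort))
    expect_true(all(ages >= 20 & ages <= 74))
})

test_that("noise-free limit gives exactly linear age features", {
    cfg <- cohortConfig(n_features_pos = 20, n_features_neg = 10,
                        n_age_features = 1, n_decreasing = 0,
                        n_gender_features = 0, n_contaminants = 0,
                        drift_amplitude = 0, noise_cv = 0, missing_rate = 0,
                        rng_seed = 5)
    sim <- generateCohort(cfg)
    xs <- sampleInjections(sim$cohort)
    f <- sim$truth$age_features$feature_id[1]
    fitres <- stats::lm(intensities(xs)[f, ] ~ subjectAge(xs))
    expect_lt(max(abs(stats::residuals(fitres))), 1e-8)
})

test_that("dilution injections scale with volume and blanks carry contaminant signal", {
    cfg <- smallCohortConfig(3, noise_cv = 0.1)
    sim <- generateCohort(cfg)
    m <- intensities(sim$cohort)
    dil <- sampleType(sim$cohort) == "dilution"
    vols <- injectionVolume(sim$cohort)[dil]
    noncont <- setdiff(rownames(m), sim$truth$contaminant_ids)
    r <- apply(m[noncont, dil], 1L, function(y) stats::cor(vols, y))
    expect_gt(mean(r), 0.9)

    blk <- sampleType(sim$cohort) == "blank"
    cont_blank <- rowMeans(m[sim$truth$contaminant_ids, blk, drop = FALSE])
    non_blank <- rowMeans(m[noncont, blk, drop = FALSE])
    expect_gt(min(cont_blank) / max(non_blank), 10)
})

test_that("slope signs of planted features are recoverable by regression", {
    hits <- 0L; total <- 0L
    for (s in 1:5) {
        cfg <- smallCohortConfig(s, effect_r2 = 0.4, drift_amplitude = 0,
                                 missing_rate = 0)
        sim <- generateCohort(cfg)
        xs <- sampleInjections(sim$cohort)
        reg <- perFeatureRegression(xs)
        idx <- match(sim$truth$age_features$feature_id, reg$feature_id)
        hits <- hits + sum(reg$direction[idx] == sim$truth$age_features$direction)
        total <- total + length(idx)
    }
    expect_gte(hits / total, 0.95)
})

test_that("class assignment plants enrichment and respects the catalogue", {
    cfg <- smallCohortConfig(9)
    sim <- generateCohort(cfg)
    cls <- generateSpectralClasses(sim$truth, cfg)
    expect_identical(sort(cls$feature_id), sort(rownames(sim$cohort)))
    expect_true(all(cls$class_path %in% classCatalogue(cfg@n_classes)))
    expect_length(classCatalogue(190L), 190L)

    # odds ratio 1 removes the planted excess (null case, in expectation)
    cfg0 <- smallCohortConfig(9, class_odds_ratio = 1)
    cls0 <- generateSpectralClasses(sim$truth, cfg0)
    enr <- attr(cls0, "enriched_classes")
    age_ids <- sim$truth$age_features$feature_id
    f_age <- mean(cls0$class_path[cls0$feature_id %in% age_ids] %in% enr)
    f_bg <- mean(cls0$class_path %in% enr)
    expect_lt(abs(f_age - f_bg), 0.35)  # both near 5/190 under the null
})

test_that("ontology fixture contains pruning and case-normalisation material", {
    tab <- generateOntologyFixture(paste0("cpd", 1:10), seed = 4)
    expect_true(any(startsWith(tab$path, "Disposition/Source")))
    first <- tab$path[tab$compound_id == "cpd1"]
    expect_true(any(first != tolower(first)) && any(first == tolower(first)))
    expect_identical(nrow(generateOntologyFixture(character(0))), 0L)
})
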