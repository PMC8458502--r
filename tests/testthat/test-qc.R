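. <- NULL  # quiet lints on pipe-free style

mkSet <- function(m, types, volumes = NULL, ages = NULL, run_order = NULL) {
    n <- ncol(m)
    if (is.null(rownames(m))) rownames(m) <- paste0("pos", seq_len(nrow(m)))
    colnames(m) <- paste0("i", seq_len(n))
    fd <- data.frame(ion_mode = "positive", mz = seq_len(nrow(m)) + 100,
                     rt = seq_len(nrow(m)) * 10, row.names = rownames(m))
    id <- data.frame(injection_id = colnames(m),
                     run_order = run_order %||% seq_len(n),
                     sample_type = types,
                     injection_volume = volumes %||% NA_real_,
                     subject_age = ages %||% ifelse(types == "sample", 50, NA_real_),
                     subject_gender = ifelse(types == "sample", "F", NA_character_))
    MetaboSet(m, fd, id)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("presence filter applies the 75% rule with half-minimum imputation", {
    # 41 samples; feature present in 30 (0.732 < 0.75) removed, 31 kept
    m <- matrix(100, 3, 41)
    m[1, 1:11] <- NA  # present in 30
    m[2, 1:10] <- NA  # present in 31
    m[2, 11] <- 40    # minimum observed -> impute 20
    x <- mkSet(m, rep("sample", 41))
    res <- presenceFilter(x, 0.75)
    expect_identical(removedFeatures(res$report), "pos1")
    expect_identical(nrow(res$matrix), 2L)
    expect_identical(unname(intensities(res$matrix)["pos2", 1]), 20)
    expect_false(anyNA(intensities(res$matrix)))
})

test_that("blank filter compares median blank against 1% of max sample, strictly", {
    m <- rbind(c(100, 80, 3, 2, 4),    # median blank 3 > 1 -> removed
               c(100, 90, 0, 0, 1),    # median 0 -> kept
               c(100, 50, 1, 1, 1))    # median exactly 1 = threshold -> kept
    x <- mkSet(m, c("sample", "sample", "blank", "blank", "blank"))
    res <- blankFilter(x, 0.01)
    expect_identical(removedFeatures(res$report), "pos1")
    expect_identical(rownames(res$matrix), c("pos2", "pos3"))
    expect_error(blankFilter(mkSet(matrix(1, 1, 2), rep("sample", 2))), "blank")
})

test_that("dilution filter keeps positive significant Pearson correlations only", {
    v <- c(0.5, 1, 2, 4, 8, 16, 32)
    m <- rbind(proportional = 10 * v,
               constant = rep(5, 7),
               alternating = c(6, 5, 6, 5, 6, 5, 6),
               decreasing = 100 - 3 * v)
    rownames(m) <- paste0("pos", 1:4)
    x <- mkSet(m, rep("dilution", 7), volumes = v)
    res <- dilutionFilter(x, 0.05)
    expect_identical(rownames(res$matrix), "pos1")
    d <- res$report@diagnostics
    # frozen oracle values for the alternating profile (t-distribution, 5 df)
    expect_equal(d$dilution_r[3], 0.168947645993, tolerance = 1e-9)
    expect_equal(d$dilution_p[3], 0.717261298807, tolerance = 1e-9)
    expect_gte(d$dilution_p[3], 0.05)
    expect_true(is.na(d$dilution_r[2]))  # undefined r -> removed
})

test_that("loess correction flattens drift, preserves QC means, is scale-equivariant", {
    set.seed(2)
    n <- 40
    ro <- 1:n
    types <- rep("sample", n)
    types[seq(1, n, by = 5)] <- "qc"
    drift <- 1 + 0.3 * sin(2 * pi * ro / n)
    m <- rbind(1000 * drift, 500 * drift * exp(rnorm(n, 0, 0.01)))
    x <- mkSet(m, types, run_order = ro)
    res <- loessCorrect(x, span = 0.2)
    d <- res$report@diagnostics
    expect_true(all(d$qc_cv_after < 0.2 * d$qc_cv_before))
    qc <- sampleType(x) == "qc"
    raw_mean <- rowMeans(intensities(x)[, qc])
    cor_mean <- rowMeans(intensities(res$matrix)[, qc])
    expect_lt(max(abs(cor_mean / raw_mean - 1)), 1e-9)

    # scale equivariance: c * row corrects to c * corrected row
    x10 <- x
    SummarizedExperiment::assay(x10, "intensities") <- intensities(x) * 10
    res10 <- loessCorrect(x10, span = 0.2)
    expect_equal(intensities(res10$matrix), intensities(res$matrix) * 10,
                 tolerance = 1e-12)

    # constant QC intensities leave the matrix unchanged
    mc <- matrix(100, 1, n)
    resc <- loessCorrect(mkSet(mc, types, run_order = ro), span = 0.2)
    expect_equal(unname(intensities(resc$matrix)), unname(mc), tolerance = 1e-12)

    # fewer than 4 QCs: flagged fallback, matrix unchanged
    types3 <- rep("sample", 10); types3[c(1, 5, 10)] <- "qc"
    m3 <- matrix(rep(c(100, 110, 120, 130, 140, 150, 160, 170, 180, 190), each = 1),
                 1, 10)
    res3 <- loessCorrect(mkSet(m3, types3), span = 0.2)
    expect_match(res3$report@flags, "fallback")
    expect_equal(intensities(res3$matrix), intensities(mkSet(m3, types3)))
})

test_that("cv filter uses sample sd with a strict threshold", {
    m <- rbind(c(100, 100, 100),   # cv 0 -> kept
               c(80, 100, 120),    # cv exactly 0.20 -> removed (strict <)
               c(50, 100, 150))    # cv 0.5 -> removed
    x <- mkSet(m, rep("qc", 3))
    res <- cvFilter(x, 0.20)
    expect_identical(rownames(res$matrix), "pos1")
    expect_error(cvFilter(mkSet(matrix(1, 1, 1), "qc")), ">= 2 QC")
})

test_that("blank-removal count is monotone under median inflation (brute force)", {
    # enumerate 3-blank intensity triples; raising any blank above the prior
    # median can only keep or increase the number of removals
    grid <- expand.grid(b1 = 0:3, b2 = 0:3, b3 = 0:3)
    max_sample <- 100
    thresh <- 0.01 * max_sample
    removed <- function(b) stats::median(b) > thresh
    for (i in seq_len(nrow(grid))) {
        b <- as.numeric(grid[i, ])
        med <- stats::median(b)
        for (j in 1:3) {
            b2 <- b
            b2[j] <- b2[j] + 5  # push above prior median
            if (b2[j] > med)
                expect_gte(removed(b2), removed(b))
        }
    }
})

test_that("qc chain composes stages in order and ends samples-only", {
    cfg <- smallCohortConfig(6, noise_cv = 0.05)
    sim <- generateCohort(cfg)
    res <- runQCChain(sim$cohort, pipelineConfig())
    expect_named(res$reports, c("presence", "blank", "dilution", "loess", "cv"))
    # all contaminants removed at the blank stage
    expect_true(all(sim$truth$contaminant_ids %in%
                        removedFeatures(res$reports$blank)))
    # composition bookkeeping
    expect_identical(res$reports$presence@nOut, res$reports$blank@nIn)
    expect_identical(res$reports$blank@nOut, res$reports$dilution@nIn)
    expect_true(all(sampleType(res$matrix) == "sample"))
    expect_false(anyNA(intensities(res$matrix)))
    # errors propagate with the stage name
    noqc <- sim$cohort[, sampleType(sim$cohort) != "blank"]
    expect_error(runQCChain(noqc, pipelineConfig()), "stage 'blank'")
})

test_that("extreme thresholds pass or fail everything", {
    cfg <- smallCohortConfig(8)
    sim <- generateCohort(cfg)
    s1 <- presenceFilter(sim$cohort, 1e-9)
    expect_identical(nrow(s1$matrix), nrow(sim$cohort))
    s2 <- cvFilter(loessCorrect(s1$matrix)$matrix, 1 - 1e-9)
    expect_gt(nrow(s2$matrix), 0.95 * nrow(sim$cohort))
    s3 <- cvFilter(s1$matrix, 1e-9)
    expect_identical(nrow(s3$matrix), 0L)
})
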