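.newReport <- function(stage, nIn, removed, diagnostics = data.frame(),
                       flags = character()) {
    new("FilterReport", stage = stage, nIn = as.integer(nIn),
        nOut = as.integer(nIn - length(removed)),
        removedIds = as.character(removed),
        diagnostics = diagnostics, flags = flags)
}

#' Sample-presence filter
#'
#' Keeps a feature only when it was observed (non-missing) in at least
#' `presence_fraction` of the study-sample injections; the remaining
#' missing sample cells of kept features are imputed with half the
#' feature's minimum observed sample intensity, so downstream correlation
#' and LOESS stages see complete rows.
#'
#' @param x a [MetaboSet-class] containing sample injections
#' @param presence_fraction minimum observed fraction (default 0.75)
#' @return `list(matrix = <filtered MetaboSet>, report = <FilterReport>)`
#' @export
presenceFilter <- function(x, presence_fraction = 0.75) {
    smp <- which(sampleType(x) == "sample")
    if (!length(smp))
        stop("presence filter requires sample injections")
    m <- intensities(x)
    frac <- rowMeans(!is.na(m[, smp, drop = FALSE]))
    removed <- rownames(x)[frac < presence_fraction]
    diag <- data.frame(feature_id = rownames(x), presence = frac,
                       stringsAsFactors = FALSE)
    keep <- x[frac >= presence_fraction, ]
    mk <- intensities(keep)
    for (i in seq_len(nrow(mk))) {
        row <- mk[i, smp]
        if (anyNA(row)) {
            half_min <- min(row, na.rm = TRUE) / 2
            row[is.na(row)] <- half_min
            mk[i, smp] <- row
        }
    }
    SummarizedExperiment::assay(keep, "intensities") <- mk
    list(matrix = keep, report = .newReport("presence", nrow(x), removed, diag))
}

#' Blank-contaminant filter
#'
#' Removes a feature when its median intensity across the solvent-blank
#' injections exceeds `blank_fraction` of the maximum intensity across the
#' study samples (strict `>`, so a median exactly at the threshold is
#' kept).
#'
#' @param x a [MetaboSet-class] with at least one blank injection
#' @param blank_fraction threshold fraction (default 0.01)
#' @return `list(matrix, report)` as in [presenceFilter()]
#' @export
blankFilter <- function(x, blank_fraction = 0.01) {
    blk <- which(sampleType(x) == "blank")
    smp <- which(sampleType(x) == "sample")
    if (!length(blk))
        stop("no blank injections present; skip this stage explicitly if the design has no blanks")
    if (!length(smp))
        stop("blank filter requires sample injections")
    m <- intensities(x)
    med_blank <- apply(m[, blk, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    max_sample <- apply(m[, smp, drop = FALSE], 1L, max, na.rm = TRUE)
    ratio <- med_blank / max_sample
    remove <- med_blank > blank_fraction * max_sample
    remove[is.na(remove)] <- FALSE
    diag <- data.frame(feature_id = rownames(x), median_blank = med_blank,
                       max_sample = max_sample, blank_ratio = ratio,
                       stringsAsFactors = FALSE)
    list(matrix = x[!remove, ],
         report = .newReport("blank", nrow(x), rownames(x)[remove], diag))
}

#' Dilution-series correlation filter
#'
#' Keeps a feature only when its intensity across the QC dilution ladder
#' shows a significant positive Pearson correlation with the injected
#' volume: two-sided p below `alpha` (from the t statistic
#' r*sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom) AND r > 0.  Features
#' with constant intensity across the dilution injections have undefined r
#' and are removed.
#'
#' @param x a [MetaboSet-class] with >= 3 dilution injections at distinct
#'   volumes
#' @param alpha p-value threshold (default 0.05)
#' @param log_scale correlate log volume with log intensity instead of the
#'   raw scales (default `FALSE`)
#' @return `list(matrix, report)` with per-feature `r` and `p` diagnostics
#' @export
dilutionFilter <- function(x, alpha = 0.05, log_scale = FALSE) {
    dil <- which(sampleType(x) == "dilution")
    vols <- injectionVolume(x)[dil]
    if (length(dil) < 3L || length(unique(vols)) < 3L)
        stop("dilution filter requires >= 3 dilution injections with distinct volumes")
    m <- intensities(x)[, dil, drop = FALSE]
    if (log_scale) {
        vols <- log(vols)
        m <- log(pmax(m, .Machine$double.xmin))
    }
    r <- rep(NA_real_, nrow(m))
    p <- rep(NA_real_, nrow(m))
    for (i in seq_len(nrow(m))) {
        y <- m[i, ]
        ok <- !is.na(y)
        if (sum(ok) >= 3L && stats::sd(y[ok]) > 0 && stats::sd(vols[ok]) > 0) {
            ri <- stats::cor(vols[ok], y[ok])
            n <- sum(ok)
            if (abs(ri) < 1) {
                t <- ri * sqrt((n - 2) / (1 - ri^2))
                p[i] <- 2 * stats::pt(-abs(t), df = n - 2)
            } else p[i] <- 0
            r[i] <- ri
        }
    }
    keep <- !is.na(r) & r > 0 & p < alpha
    diag <- data.frame(feature_id = rownames(x), dilution_r = r, dilution_p = p,
                       stringsAsFactors = FALSE)
    list(matrix = x[keep, ],
         report = .newReport("dilution", nrow(x), rownames(x)[!keep], diag))
}

#' Pooled-QC LOESS run-order drift correction
#'
#' For each feature, a LOESS curve (local linear fit, span expressed as a
#' fraction of the QC points) is fitted to the pooled-QC intensities
#' against run order, evaluated at every injection's run order (constant
#' extrapolation beyond the first/last QC), and each intensity is divided
#' by the curve normalised to its mean over the QC injections.  The
#' corrected row is rescaled so the feature's mean QC intensity is
#' preserved (to well within 1e-9 relative).  With fewer than 4 QC
#' injections no curve can be fitted; a constant factor is used instead
#' (leaving the row unchanged after normalisation) and the stage is
#' flagged.
#'
#' @param x a [MetaboSet-class]
#' @param span LOESS span (default 0.2)
#' @param log_scale fit on log intensities (default `FALSE`)
#' @return `list(matrix, report)`; diagnostics hold the QC CV before and
#'   after correction per feature
#' @export
loessCorrect <- function(x, span = 0.2, log_scale = FALSE) {
    qc <- which(sampleType(x) == "qc")
    ro <- runOrder(x)
    m <- intensities(x)
    flags <- character()
    cv <- function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2L || mean(v) == 0) return(NA_real_)
        stats::sd(v) / mean(v)
    }
    cv_before <- apply(m[, qc, drop = FALSE], 1L, cv)
    if (length(qc) < 4L) {
        flags <- "fallback: fewer than 4 QC injections, constant median factor applied"
        corrected <- m
    } else {
        corrected <- m
        qc_ro <- ro[qc]
        ord <- order(qc_ro)
        for (i in seq_len(nrow(m))) {
            y <- m[i, qc][ord]
            ok <- !is.na(y)
            if (sum(ok) < 4L) next
            xs <- qc_ro[ord][ok]
            ys <- if (log_scale) log(pmax(y[ok], .Machine$double.xmin)) else y[ok]
            fit <- limma::loessFit(ys, xs, span = span)$fitted
            if (log_scale) fit <- exp(fit)
            curve <- stats::approx(xs, fit, xout = ro, rule = 2)$y
            curve[curve <= 0 | is.na(curve)] <- mean(fit)
            factor <- curve / mean(curve[qc])
            row <- m[i, ] / factor
            # preserve the feature's mean QC intensity exactly
            mu_raw <- mean(m[i, qc], na.rm = TRUE)
            mu_cor <- mean(row[qc], na.rm = TRUE)
            if (is.finite(mu_raw) && is.finite(mu_cor) && mu_cor > 0)
                row <- row * (mu_raw / mu_cor)
            corrected[i, ] <- row
        }
    }
    cv_after <- apply(corrected[, qc, drop = FALSE], 1L, cv)
    out <- x
    SummarizedExperiment::assay(out, "intensities") <- corrected
    diag <- data.frame(feature_id = rownames(x), qc_cv_before = cv_before,
                       qc_cv_after = cv_after, stringsAsFactors = FALSE)
    list(matrix = out, report = .newReport("loess", nrow(x), character(), diag,
                                           flags))
}

#' QC coefficient-of-variation filter
#'
#' Keeps a feature only when the coefficient of variation of its pooled-QC
#' intensities (sample standard deviation over mean) is strictly below
#' `cv_threshold`.  Features whose QC mean is zero are removed.
#'
#' @param x a [MetaboSet-class] with >= 2 QC injections
#' @param cv_threshold CV threshold (default 0.20; strict `<`)
#' @return `list(matrix, report)`
#' @export
cvFilter <- function(x, cv_threshold = 0.20) {
    qc <- which(sampleType(x) == "qc")
    if (length(qc) < 2L)
        stop("CV filter requires >= 2 QC injections")
    m <- intensities(x)[, qc, drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
    cv <- ifelse(mu > 0, sdv / mu, Inf)
    keep <- cv < cv_threshold
    keep[is.na(keep)] <- FALSE
    diag <- data.frame(feature_id = rownames(x), qc_cv = cv,
                       stringsAsFactors = FALSE)
    list(matrix = x[keep, ],
         report = .newReport("cv", nrow(x), rownames(x)[!keep], diag))
}

#' Run the full quality-control filtering chain
#'
#' Applies, in fixed order: sample-presence filter (with half-minimum
#' imputation), blank-contaminant removal, dilution-series Pearson filter,
#' pooled-QC LOESS run-order correction, and the QC CV retention filter.
#' The returned analysis matrix contains the study samples only; QC, blank
#' and dilution injections are dropped after they have served their
#' filtering purpose.
#'
#' @param x a [MetaboSet-class] with all four injection types
#' @param config a [PipelineConfig-class]
#' @return `list(matrix = <samples-only MetaboSet>, reports = <list of
#'   FilterReport>)`
#' @examples
#' sim <- generateCohort(cohortConfig(n_features_pos = 60, n_features_neg = 40,
#'                                    n_age_features = 8, n_gender_features = 4,
#'                                    n_contaminants = 5))
#' res <- runQCChain(sim$cohort, pipelineConfig())
#' vapply(res$reports, function(r) r@nOut, integer(1))
#' @export
runQCChain <- function(x, config = pipelineConfig()) {
    stopifnot(methods::is(config, "PipelineConfig"))
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("QC chain failed at stage '%s': %s", stage,
                         conditionMessage(e)), call. = FALSE))
    }
    s1 <- run("presence", presenceFilter(x, config@presence_fraction))
    s2 <- run("blank", blankFilter(s1$matrix, config@blank_fraction))
    s3 <- run("dilution", dilutionFilter(s2$matrix, config@dilution_alpha))
    s4 <- run("loess", loessCorrect(s3$matrix, config@loess_span))
    s5 <- run("cv", cvFilter(s4$matrix, config@cv_threshold))
    final <- sampleInjections(s5$matrix)
    reports <- list(presence = s1$report, blank = s2$report,
                    dilution = s3$report, loess = s4$report, cv = s5$report)
    list(matrix = final, reports = reports)
}
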