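#' Shadow-feature all-relevant selection over a random forest
#'
#' Implements the Boruta scheme: at each iteration every still-undecided
#' feature is paired with a "shadow" copy whose values are independently
#' permuted (shadows are padded to at least 5); a random forest
#' (regression for age, classification for gender) is fitted on real plus
#' shadow columns with out-of-bag permutation importance scaled by its
#' standard error (an importance Z-score); a feature scores a hit when its
#' Z strictly exceeds the best shadow Z.  After every iteration the hit
#' count of each undecided feature is tested against Binomial(iterations,
#' 0.5) with the standard pair of exact one-sided binomial tests at level
#' 0.01, Bonferroni-adjusted across the full feature family (so the
#' family-wise error rate stays controlled even though the test is applied
#' after every iteration): hit counts
#' significantly above chance confirm the feature, significantly below
#' reject it.  Rejected features (and their shadows) leave the forest;
#' confirmed features remain in it so the competition stays realistic.
#' The loop stops when no feature is undecided or after `max_runs`
#' iterations; anything left is reported tentative, never silently
#' confirmed.
#'
#' After selection, the confirmed set is validated with a regression tree
#' ([validateSelection()]) and with the out-of-bag R-squared of a random
#' forest restricted to the confirmed features.
#'
#' @param x a [MetaboSet-class] (samples only, complete intensities) or a
#'   samples-by-features numeric matrix
#' @param target `"age"` (regression) or `"gender"` (classification); when
#'   `x` is a bare matrix, supply the response in `y`
#' @param config a [PipelineConfig-class] (uses `boruta_max_runs`,
#'   `boruta_bonferroni`, `n_trees`, `rng_seed`)
#' @param y optional explicit response vector overriding the metadata
#' @return a [BorutaResult-class]
#' @export
borutaSelect <- function(x, target = c("age", "gender"),
                         config = pipelineConfig(), y = NULL) {
    target <- match.arg(target)
    if (methods::is(x, "MetaboSet")) {
        xs <- sampleInjections(x)
        X <- t(intensities(xs))
        if (is.null(y))
            y <- if (target == "age") subjectAge(xs) else factor(subjectGender(xs))
    } else {
        X <- as.matrix(x)
        if (is.null(y))
            stop("a response vector y is required when x is a bare matrix")
        if (target == "gender") y <- factor(y)
    }
    if (anyNA(X))
        stop("predictor matrix contains missing values; run the QC chain first")
    if (ncol(X) < 2L)
        stop("Boruta needs at least 2 features")
    if (nrow(X) < 10L)
        stop("Boruta needs at least 10 samples")
    if ((is.numeric(y) && stats::sd(y) == 0) ||
        (is.factor(y) && nlevels(droplevels(y)) < 2L))
        stop("constant target")

    n_feat <- ncol(X)
    feat_ids <- colnames(X)
    if (is.null(feat_ids)) feat_ids <- paste0("V", seq_len(n_feat))
    colnames(X) <- feat_ids
    decision <- rep("tentative", n_feat)
    names(decision) <- feat_ids
    hits <- stats::setNames(integer(n_feat), feat_ids)
    z_hist <- list()
    max_runs <- config@boruta_max_runs
    iter <- 0L
    set.seed(config@rng_seed)
    alpha <- 0.01
    while (any(decision == "tentative") && iter < max_runs) {
        iter <- iter + 1L
        und <- which(decision == "tentative")
        active <- which(decision != "rejected")
        Xa <- X[, active, drop = FALSE]
        # The shadow background keeps the full feature width throughout, so
        # the best-shadow bar does not drop as features are rejected.
        n_shadow <- max(n_feat, 5L)
        sh_src <- rep_len(seq_len(n_feat), n_shadow)
        shadows <- vapply(sh_src, function(j) sample(X[, j]),
                          numeric(nrow(X)))
        colnames(shadows) <- paste0("shadow_", seq_len(n_shadow))
        dat <- data.frame(cbind(Xa, shadows), check.names = FALSE)
        dat$.y <- y
        fit <- ranger::ranger(
            dependent.variable.name = ".y", data = dat,
            num.trees = config@n_trees, importance = "permutation",
            scale.permutation.importance = TRUE,
            seed = config@rng_seed + iter,
            num.threads = 1L)
        z <- fit$variable.importance
        z_sh_max <- max(z[colnames(shadows)])
        z_real <- z[colnames(Xa)]
        hit <- stats::setNames(z_real > z_sh_max, colnames(Xa))
        hits[und] <- hits[und] + as.integer(hit[feat_ids[und]])
        zrow <- rep(NA_real_, n_feat)
        zrow[active] <- z_real
        attr(zrow, "max_shadow") <- z_sh_max
        z_hist[[iter]] <- zrow
        adj <- function(p) if (config@boruta_bonferroni) min(1, p * n_feat) else p
        for (f in und) {
            p_up <- stats::pbinom(hits[f] - 1L, iter, 0.5, lower.tail = FALSE)
            p_dn <- stats::pbinom(hits[f], iter, 0.5)
            if (adj(p_up) < alpha) decision[f] <- "confirmed"
            else if (adj(p_dn) < alpha) decision[f] <- "rejected"
        }
    }
    zm <- do.call(rbind, z_hist)
    if (is.null(zm)) zm <- matrix(NA_real_, 0L, n_feat)
    colnames(zm) <- feat_ids
    attr(zm, "max_shadow") <- vapply(z_hist, attr, numeric(1), "max_shadow")

    conf <- names(decision)[decision == "confirmed"]
    val_r2 <- NA_real_
    oob_r2 <- NA_real_
    if (length(conf) >= 1L && target == "age") {
        val_r2 <- validateSelection(X[, conf, drop = FALSE], y)
        dat <- data.frame(X[, conf, drop = FALSE], check.names = FALSE)
        dat$.y <- y
        rf <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                             num.trees = config@n_trees,
                             seed = config@rng_seed, num.threads = 1L)
        oob_r2 <- rf$r.squared
    }
    new("BorutaResult",
        decision = factor(decision, levels = c("confirmed", "tentative", "rejected")),
        hitCount = hits, nIterations = iter, zHistory = zm,
        target = target, validationR2 = val_r2, oobR2 = oob_r2,
        runInfo = list(seed = config@rng_seed, n_trees = config@n_trees,
                       max_runs = max_runs,
                       bonferroni = config@boruta_bonferroni))
}

#' Validate a selected feature set with a regression tree
#'
#' Fits a CART regression tree (depth <= `maxdepth`, minimum leaf size
#' `minbucket`) predicting the target from the confirmed features and
#' returns R^2 = 1 - SS_res/SS_tot of the fitted values against the actual
#' target.
#'
#' @param X samples-by-confirmed-features matrix (>= 1 column)
#' @param y numeric target (age in years)
#' @param maxdepth,minbucket tree size controls (defaults 5 and 5)
#' @return R^2 on the fitted data
#' @export
validateSelection <- function(X, y, maxdepth = 5L, minbucket = 5L) {
    X <- as.matrix(X)
    if (ncol(X) < 1L)
        stop("R^2 undefined: no confirmed features to validate")
    dat <- data.frame(X, check.names = FALSE)
    dat$.y <- y
    fit <- rpart::rpart(.y ~ ., data = dat,
                        control = rpart::rpart.control(
                            maxdepth = maxdepth, minbucket = minbucket,
                            minsplit = 2L * minbucket, cp = 1e-4, xval = 0L))
    pred <- stats::predict(fit)
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Per-feature linear regression on age
#'
#' Ordinary least squares of each feature's intensity on age, with a
#' two-sided t-test on the slope; the direction of change with age is the
#' slope sign.  Constant features get slope 0 and p = 1 (flagged
#' degenerate).
#'
#' @param x a [MetaboSet-class] (samples only) or features-by-samples
#'   matrix
#' @param age numeric ages; taken from the metadata when `x` is a
#'   `MetaboSet`
#' @return data.frame with columns `feature_id`, `slope`, `p_value`,
#'   `direction` (`"increasing"`/`"decreasing"`), `degenerate`
#' @export
perFeatureRegression <- function(x, age = NULL) {
    if (methods::is(x, "MetaboSet")) {
        xs <- sampleInjections(x)
        m <- intensities(xs)
        if (is.null(age)) age <- subjectAge(xs)
    } else {
        m <- as.matrix(x)
    }
    if (is.null(age) || length(age) != ncol(m))
        stop("age vector must align with sample columns")
    if (length(age) < 3L)
        stop("per-feature regression needs at least 3 samples")
    if (stats::sd(age) == 0)
        stop("zero age variance")
    n <- length(age)
    xc <- age - mean(age)
    sxx <- sum(xc^2)
    res <- lapply(seq_len(nrow(m)), function(i) {
        yv <- m[i, ]
        ok <- !is.na(yv)
        if (sum(ok) < 3L || stats::sd(yv[ok]) == 0)
            return(data.frame(feature_id = rownames(m)[i], slope = 0,
                              p_value = 1, direction = "increasing",
                              degenerate = TRUE, stringsAsFactors = FALSE))
        xi <- age[ok] - mean(age[ok])
        yi <- yv[ok]
        ni <- sum(ok)
        sxxi <- sum(xi^2)
        slope <- sum(xi * (yi - mean(yi))) / sxxi
        fitted <- mean(yi) + slope * xi
        sse <- sum((yi - fitted)^2)
        se <- sqrt(sse / (ni - 2) / sxxi)
        p <- if (se == 0) 0 else 2 * stats::pt(-abs(slope / se), df = ni - 2)
        data.frame(feature_id = rownames(m)[i], slope = slope, p_value = p,
                   direction = if (slope < 0) "decreasing" else "increasing",
                   degenerate = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
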