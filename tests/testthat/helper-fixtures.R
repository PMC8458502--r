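# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# A small but complete cohort configuration used by most module tests;
# named arguments override the scaled-down defaults.
smallCohortConfig <- function(seed = 1L, ...) {
    args <- list(n_features_pos = 120L, n_features_neg = 80L,
                 n_age_features = 10L, n_decreasing = 2L,
                 n_gender_features = 5L, n_contaminants = 10L,
                 rng_seed = seed)
    args <- utils::modifyList(args, list(...))
    do.call(cohortConfig, args)
}

# A tiny hand-built MetaboSet: 3 features x (2 samples, 1 qc, 1 blank).
toyMetaboSet <- function() {
    m <- matrix(c(10, 12, 11, 0.1,
                  20, 22, 21, 0.2,
                  5, NA, 5.5, 0.05), 3, 4, byrow = TRUE,
                dimnames = list(c("pos1", "pos2", "neg1"),
                                c("s1", "s2", "q1", "b1")))
    fd <- data.frame(ion_mode = c("positive", "positive", "negative"),
                     mz = c(100.1, 200.2, 150.5), rt = c(30, 60, 90),
                     row.names = rownames(m))
    id <- data.frame(injection_id = colnames(m), run_order = 1:4,
                     sample_type = c("sample", "sample", "qc", "blank"),
                     injection_volume = NA_real_,
                     subject_age = c(25, 60, NA, NA),
                     subject_gender = c("F", "M", NA, NA))
    MetaboSet(m, fd, id)
}

# Brute-force DTW by exhaustive enumeration of monotone warping paths
# (independent of the dynamic program under test).
bruteForceDTW <- function(a, b) {
    n <- length(a); m <- length(b)
    best <- Inf
    walk <- function(i, j, acc) {
        acc <- acc + abs(a[i] - b[j])
        if (acc >= best) return(invisible(NULL))
        if (i == n && j == m) {
            best <<- acc
            return(invisible(NULL))
        }
        if (i < n && j < m) walk(i + 1L, j + 1L, acc)
        if (i < n) walk(i + 1L, j, acc)
        if (j < m) walk(i, j + 1L, acc)
        invisible(NULL)
    }
    walk(1L, 1L, 0)
    best
}

# Exhaustive conditional (hypergeometric) enumeration of the two-sided
# Fisher exact p for a 2x2 table, independent of stats::fisher.test.
enumFisherP <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
    supp <- lo:hi
    logp <- lchoose(c1, supp) + lchoose(n - c1, r1 - supp) - lchoose(n, r1)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    p_obs <- pr[supp == a]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Adjusted Rand index between two partitions (direct contingency formula).
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    sa <- sum(choose(rowSums(tab), 2))
    sb <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    exp_idx <- sa * sb / n2
    (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

# Three well-separated planted age groups: group-specific metabolic profiles
# on top of lognormal baselines, ages in three bands.
threeGroupCohort <- function(seed = 1L, n_per = 7L, n_feat = 60L) {
    set.seed(seed)
    groups <- rep(1:3, each = n_per)
    ages <- c(sample(20:37, n_per, TRUE), sample(40:58, n_per, TRUE),
              sample(59:74, n_per, TRUE))
    base <- 10 ^ rnorm(n_feat, 5, 0.3)
    prof <- matrix(exp(rnorm(n_feat * 3, 0, 1.2)), n_feat, 3)
    m <- vapply(seq_along(groups), function(j)
        base * prof[, groups[j]] * exp(rnorm(n_feat, 0, 0.05)),
        numeric(n_feat))
    rownames(m) <- paste0("pos", seq_len(n_feat))
    colnames(m) <- sprintf("S%02d", seq_along(groups))
    list(m = m, groups = groups, ages = ages)
}
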