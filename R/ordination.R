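#' Bray-Curtis dissimilarity between sample injections
#'
#' d(u,v) = sum|u_i - v_i| / sum(u_i + v_i) over features, bounded in
#' [0,1] for non-negative intensities.  Computed with
#' [vegan::vegdist()].
#'
#' @param x a [MetaboSet-class] (samples only) or a numeric
#'   features-by-samples matrix with non-negative entries
#' @return a `dist` object with `attr(, "metric") == "bray"`
#' @export
brayCurtis <- function(x) {
    m <- if (methods::is(x, "MetaboSet")) intensities(x) else as.matrix(x)
    if (anyNA(m))
        stop("Bray-Curtis requires complete intensities; impute or filter first")
    if (any(m < 0))
        stop("Bray-Curtis is undefined for negative intensities")
    if (any(colSums(m) == 0))
        stop("Bray-Curtis is undefined for a pair with all-zero sum: column(s) ",
             paste(colnames(m)[colSums(m) == 0], collapse = ", "))
    d <- vegan::vegdist(t(m), method = "bray")
    attr(d, "metric") <- "bray"
    d
}

# Centered constraint design from a data.frame: numeric columns z-scored,
# two-level factors/characters encoded as one centered indicator.
.constraintDesign <- function(constraints) {
    stopifnot(is.data.frame(constraints))
    cols <- lapply(names(constraints), function(nm) {
        v <- constraints[[nm]]
        if (is.numeric(v)) {
            if (stats::sd(v) == 0)
                stop("constraint '", nm, "' is constant")
            (v - mean(v)) / stats::sd(v)
        } else {
            f <- factor(v)
            if (nlevels(f) < 2L)
                stop("constraint '", nm, "' is constant")
            ind <- as.numeric(f == levels(f)[2L])
            ind - mean(ind)
        }
    })
    X <- do.call(cbind, cols)
    colnames(X) <- names(constraints)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
        stop("rank-deficient constraints; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    X
}

.gowerCenter <- function(d) {
    D <- as.matrix(d)
    n <- nrow(D)
    A <- -0.5 * D^2
    J <- diag(n) - matrix(1 / n, n, n)
    J %*% A %*% J
}

.hatMatrix <- function(X) {
    X %*% solve(crossprod(X), t(X))
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of an arbitrary dissimilarity matrix on
#' covariates using the McArdle-Anderson formulation: with the
#' Gower-centred matrix G = -1/2 J D^2 J and the hat matrix H of the
#' centred constraint design, the constrained inertia is tr(HGH), the
#' constrained axes are the eigenvectors of HGH, and the residual
#' eigenvalues come from (I-H)G(I-H).  Negative eigenvalues of
#' non-Euclidean dissimilarities (such as Bray-Curtis) are retained in the
#' total inertia but excluded from axis scores; no Lingoes/Cailliez
#' correction is applied unless requested.
#'
#' Per-constraint inertia fractions are also reported, each from the hat
#' matrix of that constraint alone (the marginal share of total inertia it
#' explains).
#'
#' @param d a `dist` object (e.g. from [brayCurtis()] or [stats::dist()])
#' @param constraints data.frame of constraining variables aligned with the
#'   distance labels; numeric columns are z-scored, two-level factors
#'   encoded as a centred indicator
#' @param correction `"none"` (default, the common default behaviour for
#'   Bray-Curtis dbRDA) or `"lingoes"` (adds the smallest constant to the
#'   squared dissimilarities that makes them Euclidean)
#' @return an [OrdinationResult-class]
#' @examples
#' y <- c(1, 2, 3, 5, 8, 9)
#' d <- stats::dist(y)
#' fit <- dbrdaFit(d, data.frame(age = y))
#' constrainedFraction(fit)[["total"]]  # 1 (perfect constraint)
#' @export
dbrdaFit <- function(d, constraints, correction = c("none", "lingoes")) {
    correction <- match.arg(correction)
    D <- as.matrix(d)
    n <- nrow(D)
    if (nrow(constraints) != n)
        stop("constraint rows (", nrow(constraints),
             ") do not align with distance labels (", n, ")")
    if (correction == "lingoes") {
        G0 <- .gowerCenter(stats::as.dist(D))
        neg <- min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values)
        if (neg < 0) {
            off <- row(D) != col(D)
            D2 <- D^2
            D2[off] <- D2[off] + 2 * abs(neg)
            D <- sqrt(D2)
        }
    }
    X <- .constraintDesign(constraints)
    G <- .gowerCenter(stats::as.dist(D))
    H <- .hatMatrix(X)
    q <- ncol(X)
    HGH <- H %*% G %*% H
    IH <- diag(n) - H
    RGR <- IH %*% G %*% IH
    total <- sum(diag(G))
    tr_c <- sum(diag(HGH))
    tr_r <- total - tr_c
    eig_c <- eigen(HGH, symmetric = TRUE)
    keep <- which(eig_c$values > max(eig_c$values) * 1e-10 & eig_c$values > 0)
    keep <- utils::head(keep, q)
    scores <- eig_c$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(eig_c$values[keep]), length(keep))
    rownames(scores) <- rownames(D)
    colnames(scores) <- paste0("dbRDA", seq_along(keep))
    eig_r <- eigen(RGR, symmetric = TRUE, only.values = TRUE)$values
    eig_r <- eig_r[abs(eig_r) > max(abs(eig_r), 1) * 1e-12]
    frac <- vapply(seq_len(q), function(j) {
        Hj <- .hatMatrix(X[, j, drop = FALSE])
        sum(diag(Hj %*% G %*% Hj)) / total
    }, numeric(1))
    names(frac) <- colnames(X)
    frac <- c(frac, total = tr_c / total)
    pf <- (tr_c / q) / (tr_r / (n - q - 1))
    new("OrdinationResult",
        constrainedEig = eig_c$values[keep],
        residualEig = eig_r,
        siteScores = scores,
        constrainedFraction = pmin(pmax(frac, 0), 1),
        totalInertia = total,
        pseudoF = pf,
        permutationP = stats::setNames(numeric(0), character(0)),
        G = G, constraints = X, metric = attr(d, "metric") %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pseudoF <- function(G, X) {
    n <- nrow(G)
    q <- ncol(X)
    H <- .hatMatrix(X)
    tr_c <- sum(H * G)            # tr(HGH) = tr(HG) for idempotent symmetric H
    tot <- sum(diag(G))
    tr_r <- tot - tr_c
    if (tr_r < abs(tot) * 1e-12)  # perfect fit up to round-off
        return(Inf)
    (tr_c / q) / (tr_r / (n - q - 1))
}

#' Permutation tests for a fitted dbRDA model
#'
#' Empirical p-values with the add-one estimator
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), which can never
#' return zero.  The `"model"` test permutes the sample identities of the
#' whole constraint design; each per-constraint test permutes the rows of
#' that constraint only, holding the others fixed, and recomputes the
#' full-model pseudo-F.
#'
#' @param ord an [OrdinationResult-class] from [dbrdaFit()]
#' @param n_permutations number of permutations (default 999)
#' @param seed RNG seed
#' @return the [OrdinationResult-class] with its `permutationP` slot filled
#'   (named: `"model"` plus one entry per constraint)
#' @export
permutationTest <- function(ord, n_permutations = 999L, seed = 1L) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    if (n_permutations < 1L)
        stop("n_permutations must be at least 1")
    G <- ord@G
    X <- ord@constraints
    n <- nrow(G)
    f_obs <- .pseudoF(G, X)
    if (is.nan(f_obs))
        stop("pseudo-F undefined (constant constraint?)")
    set.seed(seed)
    exceed_model <- 0L
    exceed_col <- integer(ncol(X))
    for (b in seq_len(n_permutations)) {
        perm <- sample.int(n)
        if (.pseudoF(G, X[perm, , drop = FALSE]) >= f_obs)
            exceed_model <- exceed_model + 1L
        for (j in seq_len(ncol(X))) {
            Xp <- X
            Xp[, j] <- X[sample.int(n), j]
            if (.pseudoF(G, Xp) >= f_obs)
                exceed_col[j] <- exceed_col[j] + 1L
        }
    }
    p <- c((1 + exceed_model) / (1 + n_permutations),
           (1 + exceed_col) / (1 + n_permutations))
    names(p) <- c("model", colnames(X))
    ord@permutationP <- p
    methods::validObject(ord)
    ord
}

#' Post-hoc goodness of fit of a variable on ordination axes
#'
#' Fits a variable onto the site scores of the first `axes` constrained
#' axes.  For a numeric variable, r2 is the squared multiple correlation
#' of the least-squares projection of the variable onto the axis-score
#' space; for a factor, r2 = 1 - SS_within/SS_total of the axis scores
#' grouped by level.  The empirical p permutes the variable with the same
#' add-one estimator as [permutationTest()].  A zero-variance variable is
#' defined to have r2 = 0 and p = 1.
#'
#' @param ord an [OrdinationResult-class]
#' @param variable numeric vector or factor, aligned with the sites
#' @param n_permutations permutations for the empirical p (default 999)
#' @param seed RNG seed
#' @param axes number of leading constrained axes to use (default 2)
#' @return `list(r2 = <numeric>, p = <numeric>)`
#' @export
envfitVariable <- function(ord, variable, n_permutations = 999L, seed = 1L,
                           axes = 2L) {
    stopifnot(methods::is(ord, "OrdinationResult"))
    S <- ord@siteScores
    if (ncol(S) < 1L)
        stop("no constrained axes with positive eigenvalues")
    S <- S[, seq_len(min(axes, ncol(S))), drop = FALSE]
    r2_of <- function(v) {
        if (is.numeric(v)) {
            if (stats::sd(v) == 0) return(0)
            fit <- stats::lm.fit(cbind(1, S), v)
            1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
        } else {
            f <- factor(v)
            if (nlevels(f) < 2L) return(0)
            tot <- sum(scale(S, scale = FALSE)^2)
            within <- sum(vapply(levels(f), function(l) {
                Sg <- S[f == l, , drop = FALSE]
                sum(scale(Sg, scale = FALSE)^2)
            }, numeric(1)))
            1 - within / tot
        }
    }
    r2 <- r2_of(variable)
    if ((is.numeric(variable) && stats::sd(variable) == 0) ||
        (!is.numeric(variable) && nlevels(factor(variable)) < 2L))
        return(list(r2 = 0, p = 1))
    set.seed(seed)
    exceed <- sum(vapply(seq_len(n_permutations), function(b)
        r2_of(variable[sample.int(length(variable))]) >= r2, logical(1)))
    list(r2 = r2, p = (1 + exceed) / (1 + n_permutations))
}
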