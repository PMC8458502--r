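#' Hierarchical clustering of samples
#'
#' Clusters the sample injections on Bray-Curtis dissimilarity with Ward.D
#' agglomeration (the classic Lance-Williams Ward update on the unsquared
#' dissimilarities, as distinct from Ward.D2), and cuts the tree into `k`
#' groups -- the three-age-group view uses k = 3.
#'
#' @param x a [MetaboSet-class] (samples only, non-negative complete
#'   intensities) or features-by-samples matrix
#' @param k number of groups to cut (default 3)
#' @return `list(dendrogram = <hclust>, groups = <named integer vector>)`
#' @export
clusterSamples <- function(x, k = 3L) {
    m <- if (methods::is(x, "MetaboSet")) intensities(x) else as.matrix(x)
    if (k > ncol(m))
        stop("k (", k, ") exceeds the number of samples (", ncol(m), ")")
    d <- brayCurtis(m)
    hc <- stats::hclust(d, method = "ward.D")
    list(dendrogram = hc, groups = stats::cutree(hc, k = k))
}

#' Hierarchical clustering of features
#'
#' Clusters features on Euclidean distances between per-feature z-scored
#' profiles (Ward.D agglomeration).  Zero-variance features are given an
#' all-zero z-profile and flagged.
#'
#' @param x a [MetaboSet-class] or features-by-samples matrix (>= 2
#'   features)
#' @return an `hclust` object; flagged zero-variance features in
#'   `attr(, "degenerate_features")`
#' @export
clusterFeatures <- function(x) {
    m <- if (methods::is(x, "MetaboSet")) intensities(x) else as.matrix(x)
    if (nrow(m) < 2L)
        stop("feature clustering needs at least 2 features")
    sds <- apply(m, 1L, stats::sd)
    z <- m
    ok <- sds > 0
    z[ok, ] <- t(scale(t(m[ok, , drop = FALSE])))
    z[!ok, ] <- 0
    hc <- stats::hclust(stats::dist(z), method = "ward.D")
    attr(hc, "degenerate_features") <- rownames(m)[!ok]
    hc
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with absolute-difference local cost and
#' symmetric steps (diagonal, horizontal, vertical), no warping window.
#'
#' @param a,b non-empty numeric series
#' @return the minimal cumulative alignment cost (non-negative)
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))  # 0
#' @export
dtwDistance <- function(a, b) {
    if (!length(a) || !length(b))
        stop("DTW requires non-empty series")
    n <- length(a); m <- length(b)
    cost <- abs(outer(a, b, `-`))
    D <- matrix(Inf, n + 1L, m + 1L)
    D[1L, 1L] <- 0
    for (i in seq_len(n))
        for (j in seq_len(m))
            D[i + 1L, j + 1L] <- cost[i, j] +
                min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    D[n + 1L, m + 1L]
}

#' DTW-based linearity score of an age profile
#'
#' Measures how far a feature's age-ordered intensity profile departs from
#' a straight line: the profile and its own least-squares line (as a
#' function of age) are both z-scored and compared by DTW, normalised by
#' the series length.  An exactly linear profile scores 0; a constant
#' profile is defined to score 0 and is flagged degenerate.
#'
#' @param profile numeric intensities, one per sample
#' @param ages numeric ages aligned with `profile`
#' @return non-negative score; `attr(, "degenerate")` is `TRUE` for a
#'   constant profile
#' @export
linearityScore <- function(profile, ages) {
    stopifnot(length(profile) == length(ages))
    if (length(profile) < 3L)
        stop("linearity score needs at least 3 samples")
    ord <- order(ages)
    y <- profile[ord]
    x <- ages[ord]
    if (stats::sd(y) == 0) {
        out <- 0
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    zy <- as.numeric(scale(y))
    line <- stats::fitted(stats::lm(y ~ x))
    zl <- if (stats::sd(line) > 0) as.numeric(scale(line)) else rep(0, length(line))
    out <- dtwDistance(zy, zl) / length(y)
    attr(out, "degenerate") <- FALSE
    out
}
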