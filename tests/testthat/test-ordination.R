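test_that("bray-curtis closed forms and domain errors", {
    expect_equal(as.numeric(brayCurtis(cbind(c(1, 0), c(0, 1)))), 1)
    expect_equal(as.numeric(brayCurtis(cbind(c(2, 2), c(2, 2)))), 0)
    expect_equal(as.numeric(brayCurtis(cbind(c(2, 2), c(1, 1)))), 2 / 6)
    expect_error(brayCurtis(cbind(c(-1, 1), c(1, 1))), "negative")
    expect_error(brayCurtis(cbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("euclidean dbRDA equals classical RDA on the raw table", {
    set.seed(42)
    for (i in 1:10) {
        Y <- matrix(rnorm(60), 10, 6)
        X <- data.frame(a = rnorm(10), b = rnorm(10))
        d <- stats::dist(Y)
        fit <- dbrdaFit(d, X)
        # direct regression oracle on the centred table
        Yc <- scale(Y, scale = FALSE)
        Xc <- scale(cbind(X$a, X$b))
        H <- Xc %*% solve(crossprod(Xc), t(Xc))
        frac <- sum((H %*% Yc)^2) / sum(Yc^2)
        expect_equal(constrainedFraction(fit)[["total"]], frac, tolerance = 1e-10)
        # per-axis eigenvalues match the singular values of the fitted table
        sv <- svd(H %*% Yc)$d
        ev <- eigenvalues(fit)$constrained
        expect_equal(ev, (sv^2)[seq_along(ev)], tolerance = 1e-8)
        # total inertia = constrained + residual exactly
        expect_equal(fit@totalInertia,
                     sum(eigenvalues(fit)$constrained) +
                         sum(eigenvalues(fit)$residual),
                     tolerance = 1e-8 * fit@totalInertia)
    }
})

test_that("dbRDA agrees with an independent implementation on Bray-Curtis", {
    set.seed(7)
    m <- matrix(runif(30 * 12, 1, 100), 30, 12)
    age <- rnorm(12)
    fit <- dbrdaFit(brayCurtis(m), data.frame(age = age))
    ref <- vegan::dbrda(brayCurtis(m) ~ age)
    expect_equal(constrainedFraction(fit)[["total"]],
                 ref$CCA$tot.chi / ref$tot.chi, tolerance = 1e-8)
})

test_that("perfect constraint explains everything; rank deficiency is named", {
    y <- c(1, 2, 3, 5, 8, 9, 11, 14, 17, 21, 25, 30)
    fit <- dbrdaFit(stats::dist(y), data.frame(age = y))
    expect_equal(constrainedFraction(fit)[["total"]], 1, tolerance = 1e-10)
    p <- permutationTest(fit, 999, seed = 2)@permutationP
    expect_equal(unname(p[["age"]]), 1 / 1000)
    expect_error(dbrdaFit(stats::dist(y), data.frame(a = y, b = 2 * y)),
                 "collinear.*b")
    expect_error(dbrdaFit(stats::dist(y), data.frame(a = rep(1, 12))),
                 "constant")
})

test_that("permutation p is super-uniform under the null", {
    set.seed(31)
    n <- 15
    p_at_05 <- mean(vapply(1:100, function(b) {
        Y <- matrix(rnorm(n * 4), n, 4)
        x <- rnorm(n)
        fit <- dbrdaFit(stats::dist(Y), data.frame(x = x))
        permutationTest(fit, 99, seed = b)@permutationP[["x"]] <= 0.05
    }, logical(1)))
    expect_lte(p_at_05, 0.1)
})

test_that("envfit goodness of fit matches direct oracles", {
    set.seed(3)
    m <- matrix(runif(30 * 10, 1, 100), 30, 10)
    age <- rnorm(10); gender <- rep(c("M", "F"), 5)
    fit <- dbrdaFit(brayCurtis(m), data.frame(age = age, gender = gender))
    S <- siteScores(fit)[, 1:2]

    # variable equal to axis-1 scores projects perfectly
    expect_equal(envfitVariable(fit, S[, 1], 49, seed = 1)$r2, 1, tolerance = 1e-10)

    # factor r2 equals the between-group SS fraction computed directly
    f <- factor(gender)
    tot <- sum(scale(S, scale = FALSE)^2)
    within <- sum(vapply(levels(f), function(l)
        sum(scale(S[f == l, , drop = FALSE], scale = FALSE)^2), numeric(1)))
    expect_equal(envfitVariable(fit, f, 49, seed = 1)$r2, 1 - within / tot,
                 tolerance = 1e-12)

    # independent cross-check against vegan's implementation
    ev <- vegan::envfit(S, data.frame(age = age), permutations = 49)
    expect_equal(envfitVariable(fit, age, 49, seed = 1)$r2,
                 unname(ev$vectors$r), tolerance = 1e-10)

    # zero-variance variable is defined to (0, 1)
    expect_identical(envfitVariable(fit, rep(2, 10)), list(r2 = 0, p = 1))
})

test_that("orthogonal planted effects give near-additive constrained fractions", {
    set.seed(12)
    n <- 40
    age <- seq(-1, 1, length.out = n)
    gender <- rep(c(-0.5, 0.5), n / 2)
    Y <- cbind(outer(age, rep(1, 5)) + matrix(rnorm(n * 5, 0, .5), n, 5),
               outer(gender, rep(1, 3)) + matrix(rnorm(n * 3, 0, .5), n, 3))
    d <- stats::dist(Y)
    both <- dbrdaFit(d, data.frame(age = age, gender = gender))
    fr <- constrainedFraction(both)
    expect_lt(abs(fr[["age"]] + fr[["gender"]] - fr[["total"]]), 0.02)
})
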