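test_that("uncertainties follow the detection-limit model", {
    X <- matrix(c(0.05, 2.0), 1, 2, dimnames = list(NULL, c("a", "b")))
    U <- buildUncertainty(X, c(a = 0.1, b = 0.1), errorFraction = 0.035)
    expect_close(U[1, 1], 5 / 6 * 0.1)        # C <= MDL
    expect_close(U[1, 1], 0.0833333, tol = 1e-5)
    expect_close(U[1, 2], sqrt(0.1^2 + (0.035 * 2)^2))
    expect_close(U[1, 2], 0.1220656, tol = 1e-5)
    # zero MDL limit: u = errorFraction * C
    U0 <- buildUncertainty(matrix(1, 1, 1), 0, errorFraction = 0.035)
    expect_close(U0[1, 1], 0.035)
    expect_error(buildUncertainty(matrix(-1, 1, 1), 0.1), "nonnegative")
    expect_error(buildUncertainty(matrix(1, 1, 1), 0.1, errorFraction = 2),
                 "errorFraction")
})

test_that("signal-to-noise matches a brute-force loop", {
    expect_close(signalToNoise(matrix(0.5, 3, 2), matrix(1, 3, 2)),
                 c(0, 0))
    expect_close(signalToNoise(matrix(2, 3, 2), matrix(1, 3, 2)),
                 c(1, 1))
    set.seed(8)
    X <- matrix(runif(60, 0, 3), 10, 6)
    U <- matrix(runif(60, 0.1, 1), 10, 6)
    brute <- numeric(6)
    for (j in 1:6) {
        acc <- 0
        for (i in 1:10)
            if (X[i, j] > U[i, j]) acc <- acc + (X[i, j] - U[i, j]) / U[i, j]
        brute[j] <- acc / 10
    }
    expect_close(signalToNoise(X, U), brute, tol = 1e-12)
    expect_error(signalToNoise(X, U * 0), "> 0")
})

test_that("the objective satisfies the residual-equals-uncertainty identity", {
    set.seed(2)
    n <- 12; m <- 5; p <- 2
    G <- matrix(runif(n * p), n, p); F <- matrix(runif(p * m), p, m)
    U <- matrix(runif(n * m, 0.2, 0.5), n, m)
    X <- G %*% F + U                       # every residual equals u_ij
    expect_close(pmfObjective(X, U, G, F), n * m)
    # robust mode caps scaled residuals at 4
    X2 <- G %*% F + 10 * U
    expect_close(pmfObjective(X2, U, G, F, robust = TRUE), 16 * n * m)
    expect_close(pmfObjective(X2, U, G, F, robust = FALSE), 100 * n * m)
})

test_that("noise-free factorizable data yield Q near zero", {
    mix <- generateSourceMixture(n = 30, m = 8, p = 3, seed = 4,
                                 noise = FALSE)
    U <- matrix(0.05, 30, 8)
    fit <- fitPMF(mix$X, U, p = 3, nStarts = 5, seed = 7)
    expect_true(fit@qTrue <= 1e-6 * 30 * 8)
    expect_true(all(fit@G >= 0) && all(fit@F >= 0))
})

test_that("the solver objective is monotonically nonincreasing and seeded", {
    mix <- generateSourceMixture(n = 40, m = 10, p = 3, seed = 5)
    fit <- fitPMF(mix$X, mix$U, p = 3, nStarts = 3, seed = 21,
                  maxIter = 800)
    expect_true(all(diff(fit@qPath) <= 1e-8 * fit@qPath[-length(fit@qPath)]))
    # bit-reproducible under a fixed seed
    fit2 <- fitPMF(mix$X, mix$U, p = 3, nStarts = 3, seed = 21,
                   maxIter = 800)
    expect_identical(fit@G, fit2@G)
    expect_identical(fit@qTrue, fit2@qTrue)
    expect_error(fitPMF(mix$X, mix$U, p = 12), "p must be")
})

test_that("three generated sources are recovered with high cosine similarity", {
    mix <- generateSourceMixture(n = 60, m = 16, p = 3, seed = 9)
    fit <- fitPMF(mix$X, mix$U, p = 3, nStarts = 10, seed = 33)
    sim <- matchFactors(fit@F, mix$F)$similarity
    expect_true(all(sim >= 0.95))
    # percent contributions: mean absolute recovery error within 10 points
    trueContrib <- function(mx) {
        M <- colSums(mx$G) * mx$F
        sweep(M, 2, colSums(M), "/") * 100
    }
    perm <- matchFactors(fit@F, mix$F)$perm
    err <- abs(factorContributions(fit)[perm, ] - trueContrib(mix))
    expect_true(mean(err) <= 10)
})

test_that("factor contributions normalize to 100 percent per parameter", {
    mix <- generateSourceMixture(n = 30, m = 8, p = 3, seed = 12)
    fit <- fitPMF(mix$X, mix$U, p = 3, nStarts = 3, seed = 2)
    fc <- factorContributions(fit)
    expect_close(colSums(fc), rep(100, 8))
    # single factor trivially owns every parameter
    fit1 <- fitPMF(mix$X, mix$U, p = 1, nStarts = 2, seed = 2)
    expect_close(as.numeric(factorContributions(fit1)), rep(100, 8))
})

test_that("factor matching is invariant to permutation of factor order", {
    set.seed(14)
    F <- matrix(runif(3 * 8), 3, 8)
    perm <- c(3, 1, 2)
    m <- matchFactors(F[perm, ], F)
    expect_close(m$similarity, rep(1, 3))
    expect_equal(m$perm, order(perm))
})

test_that("APCS-MLR recovers known source structure", {
    # single source: ~100% attribution
    one <- generateSourceMixture(n = 50, m = 8, p = 1, seed = 2)
    ap1 <- apcsMlr(one$X, nFactors = 1)
    expect_true(abs(sum(ap1$contributions) - 100) < 5)
    # orthogonal 70/30 two-source split recovered within 10 points
    mix <- generateSourceMixture(n = 80, m = 10, p = 2, seed = 5,
                                 shares = c(0.7, 0.3), background = c(0, 0))
    ap <- apcsMlr(mix$X, nFactors = 2)
    got <- sort(ap$contributions, decreasing = TRUE)
    expect_true(abs(got[1] - 70) <= 10)
    expect_true(abs(got[2] - 30) <= 10)
    expect_true(ap$r2 > 0.9)
})

test_that("varimax rotation preserves communalities", {
    mix <- generateSourceMixture(n = 60, m = 12, p = 3, seed = 6)
    ap <- apcsMlr(mix$X, nFactors = 3)
    expect_close(rowSums(ap$loadings^2), rowSums(ap$unrotated^2),
                 tol = 1e-8)
})

test_that("PMF and APCS-MLR agree on the dominant source per parameter", {
    mix <- generateSourceMixture(n = 60, m = 12, p = 3, seed = 17,
                                 background = c(0, 0.05))
    fit <- fitPMF(mix$X, mix$U, p = 3, nStarts = 10, seed = 3)
    pmfDom <- dominantFactor(factorContributions(fit), byRow = TRUE)
    ap <- apcsMlr(mix$X, nFactors = 3)
    apcsDom <- dominantFactor(ap$loadings, byRow = FALSE)
    # same partition of parameters into sources (factor ids are arbitrary)
    expect_equal(length(unique(paste(pmfDom, apcsDom))),
                 length(unique(pmfDom)))
})
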