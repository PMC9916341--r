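test_that("generation is deterministic under a fixed seed", {
    g1 <- generateSamples(seed = 77)
    g2 <- generateSamples(seed = 77)
    expect_identical(concMatrix(g1$samples), concMatrix(g2$samples))
    expect_identical(g1$truth$faciesQuadrant, g2$truth$faciesQuadrant)
    g3 <- generateSamples(seed = 78)
    expect_false(identical(concMatrix(g1$samples), concMatrix(g3$samples)))
})

test_that("metal draws honour the study ranges per group", {
    gen <- generateSamples(seed = 19)
    conc <- concMatrix(gen$samples)
    grp <- sampleGroup(gen$samples)
    cr <- conc["Cr", grp == "mining"]
    expect_true(min(cr) >= 0.02 && max(cr) <= 4.5)
    crMW <- conc["Cr", grp == "mine_water"]
    expect_true(min(crMW) >= 5.8 && max(crMW) <= 6.0)
    ni <- conc["Ni", grp == "non_mining"]
    expect_true(min(ni) >= 0.05 && max(ni) <= 3.6)
    expect_equal(as.integer(table(grp)[c("mining", "non_mining",
                                         "mine_water")]),
                 c(35L, 20L, 5L))
})

test_that("rebalanced samples pass the charge-balance screen", {
    gen <- generateSamples(seed = 55)
    bal <- icbe(gen$samples)
    expect_true(mean(bal$acceptable) >= 0.95)
})

test_that("group means converge to their targets for large n", {
    sp <- syntheticSpec(n = c(mining = 2000, non_mining = 2000,
                              mine_water = 2000),
                        facies = FALSE, balance = FALSE)
    gen <- generateSamples(sp, seed = 42)
    gs <- groupSummary(gen$samples)
    chk <- merge(gs, sp$targets, by = c("group", "parameter"))
    z <- abs(chk$mean.x - chk$mean.y) / (chk$sd.y / sqrt(2000))
    expect_true(all(z <= 3))
    # draws never escape the published ranges
    expect_true(all(chk$min.x >= chk$min.y - 1e-9))
    expect_true(all(chk$max.x <= chk$max.y + 1e-9))
})

test_that("mixing mode without noise reproduces X = G F exactly", {
    mix <- generateSourceMixture(n = 20, m = 6, p = 2, seed = 3,
                                 noise = FALSE)
    expect_close(mix$X, mix$G %*% mix$F, tol = 1e-12)
    expect_true(all(mix$U > 0))
    # requested mass shares are honoured
    sh <- generateSourceMixture(n = 40, m = 8, p = 2, seed = 3,
                                noise = FALSE, shares = c(0.7, 0.3))
    mass <- colSums(sh$G) * rowSums(sh$F)
    expect_close(mass / sum(mass), c(0.7, 0.3), tol = 1e-10)
})

test_that("truth reporting scores recovery and is permutation-invariant", {
    set.seed(9)
    F <- matrix(runif(12), 3, 4)
    r <- truthReport(recoveredF = F, trueF = F)
    expect_close(r$profileSimilarity, rep(1, 3))
    rp <- truthReport(recoveredF = F[c(2, 3, 1), ], trueF = F)
    expect_close(rp$profileSimilarity, rep(1, 3))
    # identical labels give ARI 1, independent of label names
    lab <- rep(1:3, each = 5)
    expect_close(truthReport(recoveredLabels = lab, trueLabels = lab)$ari, 1)
    expect_close(truthReport(recoveredLabels = c("a", "b", "c")[lab],
                             trueLabels = lab)$ari, 1)
    # random profiles are far from the truth (sanity floor)
    sims <- replicate(30, {
        mean(truthReport(recoveredF = matrix(runif(12), 3, 4),
                         trueF = F)$profileSimilarity)
    })
    expect_true(mean(sims) < 0.98)
    expect_true(mean(sims) < mean(r$profileSimilarity))
    # facies frequency error
    fe <- truthReport(recoveredFacies = c("Ca-HCO3" = 50, "Na-Cl" = 50),
                      trueFacies = c("Ca-HCO3" = 46.6, "Na-Cl" = 53.4))
    expect_close(fe$faciesError, 3.4)
    expect_error(truthReport(recoveredF = F, trueF = F[, 1:2]), "shapes")
})

test_that("adjusted Rand agrees with an independent contingency computation", {
    set.seed(4)
    a <- sample(1:3, 40, TRUE); b <- sample(1:3, 40, TRUE)
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
    sj <- sum(choose(colSums(tab), 2))
    exp_ <- si * sj / choose(n, 2)
    oracle <- (sumij - exp_) / ((si + sj) / 2 - exp_)
    expect_close(aquarisk:::.adjustedRand(a, b), oracle, tol = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE))
        expect_close(aquarisk:::.adjustedRand(a, b),
                     e1071::classAgreement(table(a, b))$crand, tol = 1e-10)
})
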