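test_that("IDW is exact, bounded and symmetric", {
    pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
    v <- c(1, 2, 3, 4)
    # exact at data points
    expect_close(idw(pts, v, pts), v)
    # constant field predicts the constant anywhere
    expect_close(idw(pts, rep(7, 4), cbind(runif(5), runif(5))), rep(7, 5))
    # two equidistant points with values 0 and 2 -> 1
    expect_close(idw(cbind(c(0, 2), c(0, 0)), c(0, 2), cbind(1, 0)), 1)
    # predictions bounded by the data range
    q <- cbind(runif(50, -1, 2), runif(50, -1, 2))
    p <- idw(pts, v, q)
    expect_true(all(p >= min(v) - 1e-12 & p <= max(v) + 1e-12))
    expect_warning(idw(rbind(pts, pts[1, ]), c(v, 9), cbind(0.5, 0.5)),
                   "conflicting")
})

test_that("ordinary kriging is exact, unbiased and matches a dense solve", {
    set.seed(41)
    pts <- cbind(runif(5, 0, 10), runif(5, 0, 10))
    v <- 2 + 0.5 * pts[, 1] - 0.3 * pts[, 2] + rnorm(5, 0, 0.1)
    vgm <- variogramModel("spherical", nugget = 0, sill = 1.5, range = 8)
    # exactness and zero variance at data points with nugget 0
    kr <- ordinaryKrige(pts, v, vgm, pts)
    expect_close(kr$prediction, v, tol = 1e-8)
    expect_close(kr$variance, rep(0, 5), tol = 1e-8)
    # weights sum to one for arbitrary queries
    q <- cbind(runif(7, 0, 10), runif(7, 0, 10))
    kq <- ordinaryKrige(pts, v, vgm, q)
    expect_close(rowSums(kq$weights), rep(1, 7), tol = 1e-10)
    # oracle: direct dense solve of the kriging equations per query
    for (i in seq_len(nrow(q))) {
        D <- as.matrix(dist(pts))
        G <- variogramValues(vgm, D); diag(G) <- 0
        A <- rbind(cbind(G, 1), c(rep(1, 5), 0))
        g0 <- variogramValues(vgm, sqrt((pts[, 1] - q[i, 1])^2 +
                                        (pts[, 2] - q[i, 2])^2))
        lam <- qr.solve(A, c(g0, 1))
        expect_close(kq$prediction[i], sum(lam[1:5] * v), tol = 1e-10)
        expect_close(kq$variance[i], sum(lam[1:5] * g0) + lam[6],
                     tol = 1e-10)
    }
})

test_that("kriging predictions are invariant to rigid coordinate motions", {
    set.seed(6)
    pts <- cbind(runif(8, 0, 5), runif(8, 0, 5))
    v <- rnorm(8)
    vgm <- variogramModel("exponential", nugget = 0.05, sill = 1, range = 3)
    q <- cbind(runif(4, 0, 5), runif(4, 0, 5))
    base <- ordinaryKrige(pts, v, vgm, q)$prediction
    # translation
    tr <- ordinaryKrige(pts + 100, v, vgm, q + 100)$prediction
    expect_close(tr, base, tol = 1e-9)
    # rotation by 30 degrees
    th <- pi / 6
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- ordinaryKrige(pts %*% R, v, vgm, q %*% R)$prediction
    expect_close(rot, base, tol = 1e-9)
})

test_that("variogram fitting recovers a known model approximately", {
    set.seed(10)
    vgmTrue <- variogramModel("spherical", nugget = 0.1, sill = 2,
                              range = 4)
    pts <- cbind(runif(120, 0, 10), runif(120, 0, 10))
    # draw a Gaussian field with that covariance (sill - gamma)
    D <- as.matrix(dist(pts))
    C <- vgmTrue$sill - variogramValues(vgmTrue, D)
    diag(C) <- vgmTrue$sill
    L <- chol(C + diag(1e-8, 120))
    v <- drop(t(L) %*% rnorm(120))
    emp <- empiricalVariogram(pts, v)
    fit <- fitVariogram(emp, "spherical")
    expect_true(fit$sill > 0.5 * vgmTrue$sill &&
                fit$sill < 2 * vgmTrue$sill)
    expect_true(fit$range > 1 && fit$range < 10)
    expect_error(variogramModel("spherical", nugget = 2, sill = 1,
                                range = 1), "sill")
})

test_that("five-class breaks are equal-width over the observed range", {
    c1 <- classify5(c(0.02, 2.19, runif(20, 0.02, 2.19)))
    expect_close(c1$breaks, c(0.454, 0.888, 1.322, 1.756), tol = 1e-9)
    c2 <- classify5(c(0.01, 0.91, runif(20, 0.01, 0.91)))
    expect_close(c2$breaks, c(0.19, 0.37, 0.55, 0.73), tol = 1e-9)
    expect_equal(levels(c1$class),
                 c("lowest", "low", "medium", "potentially_high", "highest"))
    expect_false(anyNA(c1$class))
    cc <- classify5(rep(3, 5))
    expect_true(cc$constant)
    expect_equal(as.character(unique(cc$class)), "lowest")
})

test_that("the grid pipeline produces a classified raster", {
    gen <- generateSamples(seed = 3)
    ras <- krigeGrid(gen$samples, "Cr", resolution = 12)
    expect_equal(nrow(ras), 144)
    expect_true(all(is.finite(ras$value)))
    expect_false(anyNA(ras$class))
    expect_s3_class(attr(ras, "variogram"), "variogram")
})
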