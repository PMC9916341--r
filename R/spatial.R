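#' Inverse distance weighted interpolation
#'
#' Weighted mean with weights \code{d^-power}; exact at data points.
#' Duplicate data points with conflicting values are averaged with a
#' warning.
#'
#' @param points two-column matrix of planar data coordinates.
#' @param values observations at \code{points}.
#' @param query two-column matrix of prediction locations.
#' @param power distance-decay exponent, > 0.
#' @return numeric vector of predictions at \code{query}.
#' @export
idw <- function(points, values, query, power = 2) {
    points <- as.matrix(points); query <- as.matrix(query)
    if (power <= 0) stop("power must be > 0")
    if (!nrow(points)) stop("need at least one data point")
    dup <- duplicated(points) | duplicated(points, fromLast = TRUE)
    if (any(dup)) {
        key <- paste(points[, 1], points[, 2])
        if (any(tapply(values, key, function(v) length(unique(v))) > 1))
            warning("duplicate points with conflicting values: averaged")
        agg <- tapply(values, key, mean)
        uq <- !duplicated(key)
        points <- points[uq, , drop = FALSE]
        values <- as.numeric(agg[paste(points[, 1], points[, 2])])
    }
    apply(query, 1, function(q) {
        d <- sqrt((points[, 1] - q[1])^2 + (points[, 2] - q[2])^2)
        if (any(d == 0)) return(values[which(d == 0)[1]])
        w <- d^(-power)
        sum(w * values) / sum(w)
    })
}

#' Variogram model
#'
#' @param model \code{"spherical"}, \code{"exponential"} or
#'   \code{"gaussian"}.
#' @param nugget,sill,range nonnegative parameters; \code{sill} is the
#'   total sill (>= nugget), \code{range} > 0.
#' @return list of class \code{"variogram"}.
#' @export
variogramModel <- function(model = c("spherical", "exponential", "gaussian"),
                           nugget, sill, range) {
    model <- match.arg(model)
    if (nugget < 0 || sill < nugget || range <= 0)
        stop("require sill >= nugget >= 0 and range > 0")
    structure(list(model = model, nugget = nugget, sill = sill,
                   range = range), class = "variogram")
}

#' Evaluate a variogram model at lag distances
#'
#' @param vgm a \code{\link{variogramModel}}.
#' @param h nonnegative lag distances.
#' @return semivariance gamma(h); gamma(0) = 0 by convention.
#' @export
variogramValues <- function(vgm, h) {
    psill <- vgm$sill - vgm$nugget
    g <- switch(vgm$model,
        spherical = ifelse(h >= vgm$range, psill,
                           psill * (1.5 * h / vgm$range -
                                    0.5 * (h / vgm$range)^3)),
        exponential = psill * (1 - exp(-3 * h / vgm$range)),
        gaussian = psill * (1 - exp(-3 * (h / vgm$range)^2)))
    out <- vgm$nugget + g
    out[h == 0] <- 0
    out
}

#' Empirical semivariogram (method of moments)
#'
#' @param points two-column coordinate matrix.
#' @param values observations.
#' @param nBins number of lag bins up to half the maximum distance.
#' @return data.frame with \code{dist} (bin mean lag), \code{gamma},
#'   \code{n} (pairs per bin).
#' @export
empiricalVariogram <- function(points, values, nBins = 12) {
    points <- as.matrix(points)
    d <- as.vector(stats::dist(points))
    g <- 0.5 * as.vector(stats::dist(values))^2
    cutoff <- max(d) / 2
    keep <- d <= cutoff & d > 0
    bins <- cut(d[keep], breaks = seq(0, cutoff, length.out = nBins + 1))
    data.frame(dist = as.numeric(tapply(d[keep], bins, mean)),
               gamma = as.numeric(tapply(g[keep], bins, mean)),
               n = as.integer(table(bins)))[!is.na(tapply(d[keep], bins, mean)), ]
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares (weights = pair counts) over nugget, partial sill
#' and range via \code{optim}.
#'
#' @param emp data.frame from \code{\link{empiricalVariogram}}.
#' @param model variogram family (default spherical).
#' @return a \code{\link{variogramModel}}.
#' @export
fitVariogram <- function(emp, model = c("spherical", "exponential",
                                        "gaussian")) {
    model <- match.arg(model)
    emp <- emp[is.finite(emp$gamma) & emp$n > 0, ]
    obj <- function(par) {
        v <- variogramModel(model, nugget = exp(par[1]),
                            sill = exp(par[1]) + exp(par[2]),
                            range = exp(par[3]))
        sum(emp$n * (variogramValues(v, emp$dist) - emp$gamma)^2)
    }
    start <- c(log(max(min(emp$gamma), 1e-8)),
               log(max(max(emp$gamma) - min(emp$gamma), 1e-8)),
               log(max(emp$dist) * 0.7))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000))
    variogramModel(model, nugget = exp(fit$par[1]),
                   sill = exp(fit$par[1]) + exp(fit$par[2]),
                   range = exp(fit$par[3]))
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (semivariogram form with the
#' unbiasedness constraint, weights summing to 1) for each query point.
#' Exact at data points when the nugget is 0. Coincident data points make
#' the system singular: one jitter-and-retry is attempted, then an error
#' is raised. Coordinates are treated as planar.
#'
#' @param points two-column coordinate matrix (>= 3 points).
#' @param values observations.
#' @param vgm a \code{\link{variogramModel}}.
#' @param query two-column matrix of prediction locations.
#' @return list with \code{prediction}, \code{variance} and
#'   \code{weights} (queries x data matrix of kriging weights).
#' @export
ordinaryKrige <- function(points, values, vgm, query) {
    points <- as.matrix(points); query <- as.matrix(query)
    n <- nrow(points)
    if (n < 3) stop("ordinary kriging needs at least 3 points")
    buildLHS <- function(pts) {
        D <- as.matrix(stats::dist(pts))
        G <- variogramValues(vgm, D)
        diag(G) <- 0
        A <- rbind(cbind(G, 1), c(rep(1, n), 0))
        A
    }
    A <- buildLHS(points)
    solveSys <- function(A, B) tryCatch(solve(A, B), error = function(e) NULL)
    d2 <- function(q) sqrt(outer(points[, 1], q[, 1], "-")^2 +
                           outer(points[, 2], q[, 2], "-")^2)
    G0 <- variogramValues(vgm, d2(query))          # n x nq
    B <- rbind(G0, 1)
    L <- solveSys(A, B)
    if (is.null(L)) {
        jit <- points + stats::runif(length(points), -1e-9, 1e-9) *
            max(1, abs(points))
        A <- buildLHS(jit)
        G0 <- variogramValues(vgm, sqrt(
            outer(jit[, 1], query[, 1], "-")^2 +
            outer(jit[, 2], query[, 2], "-")^2))
        B <- rbind(G0, 1)
        L <- solveSys(A, B)
        if (is.null(L)) stop("singular kriging system (coincident points?)")
        warning("coincident points: jittered once to solve the system")
    }
    W <- L[seq_len(n), , drop = FALSE]             # weights
    mu <- L[n + 1, ]                               # Lagrange multiplier
    pred <- drop(crossprod(W, values))
    varp <- colSums(W * G0) + mu
    varp[varp < 0 & varp > -1e-12] <- 0
    list(prediction = pred, variance = varp, weights = t(W))
}

#' Five-class equal-interval vulnerability classification
#'
#' Splits the range of a predicted surface into five equal-width classes:
#' lowest, low, medium, potentially_high, highest.
#'
#' @param values finite predicted values (grid or vector).
#' @return list with \code{class} (ordered factor per value),
#'   \code{breaks} (the four interior break points), \code{constant}
#'   (flag: degenerate single-class grid).
#' @export
classify5 <- function(values) {
    v <- values[is.finite(values)]
    if (!length(v)) stop("no finite values to classify")
    lv <- c("lowest", "low", "medium", "potentially_high", "highest")
    if (diff(range(v)) == 0) {
        cls <- factor(rep("lowest", length(values)), levels = lv,
                      ordered = TRUE)
        return(list(class = cls, breaks = numeric(0), constant = TRUE))
    }
    brk <- seq(min(v), max(v), length.out = 6)
    cls <- cut(values, breaks = brk, labels = lv, include.lowest = TRUE,
               ordered_result = TRUE)
    list(class = cls, breaks = brk[2:5], constant = FALSE)
}

#' Krige a parameter onto a regular grid and classify it
#'
#' Fits a variogram to the chosen parameter, predicts on an axis-aligned
#' grid over the sample bounding box by ordinary kriging, and applies the
#' five-class equal-interval vulnerability scheme.
#'
#' @param x a \linkS4class{WaterChemSet} with coordinates in colData.
#' @param param parameter (assay row) to interpolate.
#' @param resolution grid cells per axis.
#' @param model variogram family.
#' @return data.frame in long format: \code{x}, \code{y}, \code{value},
#'   \code{variance}, \code{class}; attributes \code{"variogram"} and
#'   \code{"breaks"}.
#' @export
krigeGrid <- function(x, param, resolution = 50,
                      model = "spherical") {
    pts <- sampleCoords(x)
    if (is.null(pts) || anyNA(pts)) stop("sample coordinates required")
    v <- concMatrix(x)[param, ]
    ok <- !is.na(v)
    pts <- pts[ok, , drop = FALSE]; v <- v[ok]
    vgm <- fitVariogram(empiricalVariogram(pts, v), model = model)
    gx <- seq(min(pts[, 1]), max(pts[, 1]), length.out = resolution)
    gy <- seq(min(pts[, 2]), max(pts[, 2]), length.out = resolution)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    kr <- ordinaryKrige(pts, v, vgm, grid)
    cl <- classify5(kr$prediction)
    out <- data.frame(x = grid[, 1], y = grid[, 2],
                      value = kr$prediction, variance = kr$variance,
                      class = cl$class)
    attr(out, "variogram") <- vgm
    attr(out, "breaks") <- cl$breaks
    out
}
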