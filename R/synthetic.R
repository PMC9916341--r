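#' Study-design synthetic specification
#'
#' Default generator configuration mirroring the surveyed three-group
#' design: 35 mining-region wells, 20 non-mining (control) wells and 5
#' mine-water samples, each parameter drawn from a truncated normal
#' matched to the published per-group range and mean +/- SD, Chadha
#' quadrant weights 46.6 / 26.6 / 23.3 / 1.6 %, charge rebalancing to
#' |ICBE| <= 5%, and the detection-limit/error-fraction uncertainty model
#' (MDL Cr 0.1, Ni 0.5 mg/L; error fraction 3.5%).
#'
#' @param n named group sizes.
#' @param quadrantWeights probabilities of the four Chadha water types
#'   (Ca-HCO3, Na-HCO3, Na-Cl, Ca-Mg-Cl); must sum to 1.
#' @param balance rescale anion totals so |ICBE| <= 5%.
#' @param facies impose the quadrant weights by cation/anion splits.
#' @param mdl named detection limits (mg/L).
#' @param errorFraction relative measurement error.
#' @return list of class \code{"syntheticSpec"}; \code{$targets} holds the
#'   per-group, per-parameter \code{min}, \code{max}, \code{mean},
#'   \code{sd} table.
#' @export
syntheticSpec <- function(n = c(mining = 35, non_mining = 20, mine_water = 5),
                          quadrantWeights = c(0.466, 0.266, 0.233, 0.016),
                          balance = TRUE, facies = TRUE,
                          mdl = c(Cr = 0.1, Ni = 0.5),
                          errorFraction = 0.035) {
    qw <- quadrantWeights / sum(quadrantWeights)
    spec <- list(n = n, quadrantWeights = qw, balance = balance,
                 facies = facies, mdl = mdl, errorFraction = errorFraction,
                 targets = .studyTargets())
    bad <- with(spec$targets,
                mean < min | mean > max | min >= max | sd < 0)
    if (any(bad)) stop("infeasible target row(s)")
    class(spec) <- "syntheticSpec"
    spec
}

## Published per-group summary statistics used as generator targets.
## columns: group, parameter, min, max, mean, sd
.studyTargets <- function() {
    g <- function(group, ...) {
        m <- matrix(c(...), ncol = 4, byrow = TRUE)
        data.frame(group = group,
                   parameter = c("pH", "depth_m", "elevation_m", "EC",
                                 "Temp", "Turbidity", "ORP", "TDS",
                                 "Na", "K", "Mg", "Ca", "PO4", "NO3",
                                 "HCO3", "Cl", "SO4", "Cr", "Ni", "Mn"),
                   min = m[, 1], max = m[, 2], mean = m[, 3], sd = m[, 4])
    }
    rbind(
        g("mining",
          7.2, 8.0, 7.4, 0.2,      30, 135, 74.0, 25.5,
          290, 495, 376, 57.8,     480, 1500, 782, 249.1,
          27.5, 31.2, 30, 1.0,     2.4, 14, 6.0, 2.7,
          140, 280, 196, 36.5,     310, 980, 503, 164.3,
          25, 210, 86, 53.1,       6.0, 12.0, 10, 1.8,
          25, 60, 40, 8.5,         25, 125, 66, 25.5,
          1.33, 8.5, 3.0, 1.9,     10, 28, 18, 4.7,
          200, 650, 293, 70.1,     75, 145, 110, 14.1,
          100, 210, 153, 27.2,     0.02, 4.5, 1.3, 1.2,
          0.4, 3.8, 1.4, 0.28,     0.05, 0.8, 0.4, 0.12),
        g("non_mining",
          7.3, 8.2, 7.71, 0.26,    27.0, 95.0, 64.6, 18.84,
          310, 500, 347, 23.92,    480, 1400, 760, 233.31,
          27.4, 30.2, 28.6, 0.76,  3.2, 12.0, 6.7, 2.83,
          160, 225, 191, 19,       310, 1000, 512.5, 174.8,
          30, 245, 152.3, 71.05,   6.0, 12.0, 9.6, 2.01,
          12, 45, 27.7, 9.90,      15, 110, 49.8, 27.65,
          1.5, 10.0, 3.5, 1.93,    10, 27, 17, 4,
          215, 580, 350, 74,       95, 145, 115, 13,
          140, 190, 161, 15,       0.02, 2.3, 0.7, 0.81,
          0.05, 3.6, 1.2, 0.23,    0.04, 0.6, 0.3, 0.10),
        g("mine_water",
          6.5, 7.2, 6.8, 0.25,     15.0, 25.0, 20.0, 3.81,
          430, 470, 452.0, 16.43,  1200, 1500, 1370, 139.6,
          27.5, 31.2, 29.2, 1.50,  33.0, 70.0, 47.6, 16.47,
          170, 260, 212.0, 38.34,  750, 980, 848.0, 84.38,
          180, 255, 213.0, 27.75,  8.0, 12.0, 10.6, 1.95,
          21, 30, 25.2, 3.19,      25, 50, 39.0, 9.62,
          1.5, 6.5, 3.7, 1.92,     10, 15, 12.8, 2.17,
          400, 630, 451.0, 30.90,  100, 125, 115.0, 9.35,
          140, 180, 159.0, 14.75,  5.8, 6.0, 5.9, 0.11,
          3.2, 5.8, 4.2, 0.52,     0.6, 1.2, 0.8, 0.21))
}

## Moments of a normal truncated to [a, b]; the normalizing mass is taken
## in whichever tail is well conditioned to avoid cancellation when the
## parent mean lies far outside the interval.
.truncMoments <- function(mu, sig, a, b) {
    al <- (a - mu) / sig; be <- (b - mu) / sig
    ## far-tail regime: the truncated normal converges to a truncated
    ## exponential anchored at the near endpoint; use its closed-form
    ## moments (the normal formulas underflow past |z| ~ 35)
    if (al > 25) return(.truncExpMoments(a, b, al / sig))
    if (be < -25) {
        m <- .truncExpMoments(-b, -a, -be / sig)
        return(c(mean = -m[[1]], sd = m[[2]]))
    }
    Z <- if (al > 0)
        stats::pnorm(al, lower.tail = FALSE) -
            stats::pnorm(be, lower.tail = FALSE)
    else stats::pnorm(be) - stats::pnorm(al)
    dphi <- stats::dnorm(al) - stats::dnorm(be)
    m <- mu + sig * dphi / Z
    v <- sig^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                  (dphi / Z)^2)
    c(mean = min(max(m, a), b), sd = sqrt(max(v, 0)))
}

## Moments of an exponential with rate r truncated to [0, w], shifted to a.
.truncExpMoments <- function(a, b, r) {
    w <- b - a
    rw <- r * w
    if (rw > 700) return(c(mean = a + 1 / r, sd = 1 / r))
    E <- expm1(rw)
    m1 <- 1 / r - w / E
    v <- 1 / r^2 - w^2 * (E + 1) / E^2
    c(mean = a + m1, sd = sqrt(max(v, 0)))
}

## Find parent (mu, sigma) whose truncation to [a, b] matches the target
## mean exactly (the truncated mean is monotone in mu and spans (a, b))
## and the target sd as closely as the family allows: for a given sigma,
## mu is solved by root finding, then sigma is optimized for the sd.
## Targets whose sd exceeds the family's maximum on the interval are
## matched in the mean with the sd saturated.
.truncFit <- function(a, b, mean, sd) {
    w <- b - a
    muFor <- function(sig) {
        f <- function(mu) .truncMoments(mu, sig, a, b)[[1]] - mean
        lo <- mean - sig; hi <- mean + sig
        for (i in 1:60) {
            if (f(lo) < 0) break
            lo <- lo - 2^i * sig
        }
        for (i in 1:60) {
            if (f(hi) > 0) break
            hi <- hi + 2^i * sig
        }
        stats::uniroot(f, c(lo, hi), tol = 1e-10 * w)$root
    }
    sdErr <- function(lsig) {
        sig <- exp(lsig)
        m <- .truncMoments(muFor(sig), sig, a, b)
        (m[[2]] - sd)^2
    }
    opt <- stats::optimize(sdErr, c(log(w / 500), log(20 * w)),
                           tol = 1e-9)
    sig <- exp(opt$minimum)
    list(mu = muFor(sig), sig = sig, sdErr = sqrt(opt$objective))
}

## Inverse-CDF truncated-normal sampling, mapped through whichever normal
## tail keeps qnorm well conditioned.
.rtrunc <- function(n, mu, sig, a, b) {
    al <- (a - mu) / sig; be <- (b - mu) / sig
    if (al > 25) {
        r <- al / sig
        u <- stats::runif(n)
        return(a - log1p(-u * (-expm1(-r * (b - a)))) / r)
    }
    if (be < -25) {
        r <- -be / sig
        u <- stats::runif(n)
        return(b + log1p(-u * (-expm1(-r * (b - a)))) / r)
    }
    z <- if (al > 0) {
        pa <- stats::pnorm(al, lower.tail = FALSE)
        pb <- stats::pnorm(be, lower.tail = FALSE)
        stats::qnorm(stats::runif(n, pb, pa), lower.tail = FALSE)
    } else {
        stats::qnorm(stats::runif(n, stats::pnorm(al), stats::pnorm(be)))
    }
    pmin(pmax(mu + sig * z, a), b)
}

#' Generate a synthetic groundwater survey
#'
#' Draws each parameter per group from a truncated normal with
#' moment-matched parent parameters, scatters wells uniformly in a 10 x 10
#' km box, optionally imposes the Chadha quadrant mixture by reallocating
#' meq between (Ca+Mg) and (Na+K) and between HCO3 and (Cl+SO4) (panel
#' totals, hence the charge balance, are preserved), and optionally
#' rescales the anion total so every sample's |ICBE| is within 5%.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{samples} (a \linkS4class{WaterChemSet}) and
#'   \code{truth} (list: \code{faciesQuadrant} per sample, the target
#'   table, seed).
#' @export
generateSamples <- function(spec = syntheticSpec(), seed = 1) {
    set.seed(seed)
    tg <- spec$targets
    groups <- names(spec$n)
    samples <- list(); meta <- list()
    idx <- 0
    faciesQ <- character(0)
    for (g in groups) {
        ng <- spec$n[[g]]
        sub <- tg[tg$group == g, ]
        draws <- sapply(seq_len(nrow(sub)), function(i) {
            r <- sub[i, ]
            fit <- .truncFit(r$min, r$max, r$mean, r$sd)
            .rtrunc(ng, fit$mu, fit$sig, r$min, r$max)
        })
        draws <- matrix(draws, nrow = ng,
                        dimnames = list(NULL, sub$parameter))
        ids <- sprintf("%s_%02d", toupper(substr(g, 1, 2)), seq_len(ng))
        if (spec$facies) {
            quad <- sample(.WATER_TYPES, ng, replace = TRUE,
                           prob = spec$quadrantWeights)
            draws <- .imposeFacies(draws, quad)
            faciesQ <- c(faciesQ, quad)
        } else faciesQ <- c(faciesQ, rep(NA_character_, ng))
        if (spec$balance) draws <- .rebalance(draws)
        samples[[g]] <- draws
        meta[[g]] <- data.frame(
            group = g,
            x = stats::runif(ng, 0, 10), y = stats::runif(ng, 0, 10),
            depth_m = draws[, "depth_m"],
            elevation_m = draws[, "elevation_m"],
            row.names = ids)
    }
    M <- do.call(rbind, unname(samples))
    meta <- do.call(rbind, unname(meta))
    conc <- t(M[, setdiff(colnames(M), c("depth_m", "elevation_m")),
                drop = FALSE])
    colnames(conc) <- rownames(meta)
    wcs <- WaterChemSet(conc, meta)
    list(samples = wcs,
         truth = list(faciesQuadrant = stats::setNames(faciesQ,
                                                       rownames(meta)),
                      targets = tg, seed = seed))
}

## Reallocate meq within the cation panel and the anion panel so each
## sample lands in its assigned Chadha quadrant. Panel meq totals are kept,
## so the ICBE of the sample is untouched. TDS is a separately drawn
## variable and is not modified.
.imposeFacies <- function(draws, quad) {
    it <- ionTable()
    meqf <- function(p) abs(it$charge[it$parameter == p]) /
        it$molar_mass[it$parameter == p]
    mf <- vapply(c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "SO4"), meqf,
                 numeric(1))
    n <- nrow(draws)
    val <- function(p) as.numeric(draws[, p]) * mf[[p]]
    ## cation panel: f = share of (Ca+Mg) in total cation meq
    caSide <- quad %in% c("Ca-HCO3", "Ca-Mg-Cl")
    fTarget <- ifelse(caSide, stats::runif(n, 0.55, 0.85),
                      stats::runif(n, 0.15, 0.45))
    cTot <- val("Na") + val("K") + val("Ca") + val("Mg")
    fNow <- (val("Ca") + val("Mg")) / cTot
    sCa <- fTarget / fNow; sNa <- (1 - fTarget) / (1 - fNow)
    draws[, "Ca"] <- draws[, "Ca"] * sCa
    draws[, "Mg"] <- draws[, "Mg"] * sCa
    draws[, "Na"] <- draws[, "Na"] * sNa
    draws[, "K"] <- draws[, "K"] * sNa
    ## anion panel: g = share of HCO3 in HCO3 + Cl + SO4 meq
    hcSide <- quad %in% c("Ca-HCO3", "Na-HCO3")
    gTarget <- ifelse(hcSide, stats::runif(n, 0.55, 0.85),
                      stats::runif(n, 0.15, 0.45))
    aTot <- val("HCO3") + val("Cl") + val("SO4")
    gNow <- val("HCO3") / aTot
    sH <- gTarget / gNow; sCl <- (1 - gTarget) / (1 - gNow)
    draws[, "HCO3"] <- draws[, "HCO3"] * sH
    draws[, "Cl"] <- draws[, "Cl"] * sCl
    draws[, "SO4"] <- draws[, "SO4"] * sCl
    draws
}

## Rescale all anions multiplicatively so the sample's ICBE equals a small
## random target within +/- 4%.
.rebalance <- function(draws) {
    it <- ionTable()
    meqf <- function(p) abs(it$charge[it$parameter == p]) /
        it$molar_mass[it$parameter == p]
    cations <- c("Na", "K", "Ca", "Mg")
    anions <- c("HCO3", "Cl", "SO4", "NO3", "PO4")
    n <- nrow(draws)
    meqSum <- function(ions) {
        m <- vapply(ions, function(p) as.numeric(draws[, p]) * meqf(p),
                    numeric(n))
        if (is.null(dim(m))) m <- matrix(m, nrow = n)
        rowSums(m)
    }
    C <- meqSum(cations); A <- meqSum(anions)
    t <- stats::runif(n, -0.04, 0.04)
    kf <- C * (1 - t) / (A * (1 + t))
    draws[, anions] <- draws[, anions] * kf
    draws
}

#' Generate a known nonnegative source mixture for receptor-model tests
#'
#' Builds block-dominant nonnegative profiles F (each source loads
#' strongly on its own subset of parameters over a weak common
#' background), nonnegative contributions G, and a data matrix
#' \code{X = G F + eps} with \code{eps ~ N(0, u)} where u follows the
#' detection-limit uncertainty model. Negative noisy values are clipped
#' at zero.
#'
#' @param n samples; @param m parameters; @param p sources.
#' @param seed integer seed.
#' @param noise add measurement noise (FALSE gives X = G F exactly).
#' @param errorFraction relative error for the uncertainty model.
#' @param mdlFrac detection limits as a fraction of each parameter's mean.
#' @param shares optional length-p vector: each source's share of the
#'   total emitted mass (G columns are rescaled to honour it).
#' @param background range of the weak off-block profile loadings;
#'   \code{c(0, 0)} gives strictly orthogonal (disjoint-support) sources.
#' @return list with \code{X}, \code{U}, \code{G}, \code{F}.
#' @export
generateSourceMixture <- function(n = 60, m = 16, p = 3, seed = 1,
                                  noise = TRUE, errorFraction = 0.035,
                                  mdlFrac = 0.02, shares = NULL,
                                  background = c(0.02, 0.15)) {
    set.seed(seed)
    blocks <- split(seq_len(m), rep(seq_len(p), length.out = m))
    F <- matrix(stats::runif(p * m, background[1], background[2]), p, m)
    for (k in seq_len(p))
        F[k, blocks[[k]]] <- stats::runif(length(blocks[[k]]), 0.8, 1.5)
    G <- matrix(stats::rgamma(n * p, shape = 2, rate = 1), n, p)
    if (!is.null(shares)) {
        if (length(shares) != p) stop("shares must have length p")
        shares <- shares / sum(shares)
        mass <- colSums(G) * rowSums(F)
        G <- sweep(G, 2, shares * sum(mass) / mass, "*")
    }
    X0 <- G %*% F
    colnames(X0) <- paste0("P", seq_len(m))
    mdl <- colMeans(X0) * mdlFrac
    names(mdl) <- colnames(X0)
    U <- buildUncertainty(X0, mdl, errorFraction)
    X <- if (noise) pmax(X0 + stats::rnorm(n * m, 0, U), 0) else X0
    dimnames(X) <- dimnames(X0)
    list(X = X, U = U, G = G, F = F)
}

#' Generate well-separated Gaussian blobs with a metal-burden gradient
#'
#' Used for clustering recovery: \code{sizes} samples per blob around
#' \code{centers} (rows), isotropic sd \code{sd}. Burden increases with
#' blob index.
#'
#' @param sizes samples per blob.
#' @param centers blob centers, blobs x variables (default: three blobs in
#'   Cr/Ni/Mn space with increasing burden).
#' @param sd isotropic within-blob standard deviation.
#' @param seed integer seed.
#' @return list with \code{M} (samples x variables), \code{labels}.
#' @export
generateBlobs <- function(sizes = c(12, 8, 40),
                          centers = rbind(c(0.10, 0.5, 0.05),
                                          c(1.00, 1.5, 0.30),
                                          c(4.00, 3.0, 0.70)),
                          sd = 0.05, seed = 1) {
    set.seed(seed)
    colnames(centers) <- colnames(centers) %||% c("Cr", "Ni", "Mn")
    M <- do.call(rbind, lapply(seq_along(sizes), function(b) {
        matrix(stats::rnorm(sizes[b] * ncol(centers),
                            mean = rep(centers[b, ], each = sizes[b]),
                            sd = sd),
               nrow = sizes[b])
    }))
    M <- pmax(M, 1e-4)
    colnames(M) <- colnames(centers)
    list(M = M, labels = rep(seq_along(sizes), sizes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery metrics against generator truth
#'
#' Cosine similarity of recovered versus true source profiles (after
#' exhaustive factor matching), adjusted Rand index of cluster labels, and
#' absolute water-type frequency error.
#'
#' @param recoveredF,trueF profile matrices (factors x parameters), or NULL.
#' @param recoveredLabels,trueLabels cluster labels, or NULL.
#' @param recoveredFacies,trueFacies water-type frequency tables (named
#'   percent vectors), or NULL.
#' @return list with \code{profileSimilarity}, \code{ari},
#'   \code{faciesError} (max absolute percent difference); NULL entries
#'   where inputs were not given.
#' @export
truthReport <- function(recoveredF = NULL, trueF = NULL,
                        recoveredLabels = NULL, trueLabels = NULL,
                        recoveredFacies = NULL, trueFacies = NULL) {
    out <- list(profileSimilarity = NULL, ari = NULL, faciesError = NULL)
    if (!is.null(recoveredF) && !is.null(trueF)) {
        if (!all(dim(recoveredF) == dim(trueF)))
            stop("profile matrix shapes differ")
        out$profileSimilarity <- matchFactors(recoveredF, trueF)$similarity
    }
    if (!is.null(recoveredLabels) && !is.null(trueLabels)) {
        if (length(recoveredLabels) != length(trueLabels))
            stop("label lengths differ")
        out$ari <- .adjustedRand(recoveredLabels, trueLabels)
    }
    if (!is.null(recoveredFacies) && !is.null(trueFacies)) {
        types <- union(names(recoveredFacies), names(trueFacies))
        rv <- stats::setNames(rep(0, length(types)), types)
        tv <- rv
        rv[names(recoveredFacies)] <- recoveredFacies
        tv[names(trueFacies)] <- trueFacies
        out$faciesError <- max(abs(rv - tv))
    }
    out
}

## Adjusted Rand index (Hubert & Arabie).
.adjustedRand <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    if (maxidx == expected) return(1)
    (sumij - expected) / (maxidx - expected)
}
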