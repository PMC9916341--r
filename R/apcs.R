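#' APCS-MLR source apportionment
#'
#' Absolute principal component scores with multilinear regression.
#' Variables are z-scored, a PCA is taken on the correlation matrix, the
#' retained component loadings are varimax-rotated, and absolute scores are
#' obtained by scoring an artificial all-zero-concentration sample and
#' subtracting its scores from every sample's scores. A least-squares
#' regression of the response (by default the total measured burden, the
#' row sum of \code{X}) on the absolute scores converts factors into
#' percent source contributions:
#' \code{100 * mean(b_k * APCS_k) / mean(fitted)}.
#'
#' @param X data matrix, samples x parameters.
#' @param nFactors number of components to retain (<= ncol(X)).
#' @param rotate logical; varimax-rotate the retained loadings (default).
#' @param response \code{"total"} (regress the row-sum burden) or
#'   \code{"perSpecies"} (one regression per parameter).
#' @return list with \code{loadings} (rotated, parameters x factors),
#'   \code{unrotated} (parameters x factors), \code{scores} (rotated
#'   component scores), \code{apcs} (absolute scores), \code{contributions}
#'   (percent per factor; a matrix parameters x factors for
#'   \code{"perSpecies"}), \code{unexplained} (percent), \code{r2}
#'   (regression R-squared), \code{model} (the lm fit or list of fits).
#' @export
apcsMlr <- function(X, nFactors, rotate = TRUE,
                    response = c("total", "perSpecies")) {
    response <- match.arg(response)
    X <- as.matrix(X)
    if (nFactors > ncol(X)) stop("nFactors exceeds the number of parameters")
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    if (any(sdv == 0)) stop("constant column; correlation matrix is singular")
    Z <- scale(X, center = mu, scale = sdv)
    pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    k <- nFactors
    ## component loadings = eigenvector * singular sd (correlation scale)
    L0 <- pr$rotation[, seq_len(k), drop = FALSE] %*%
        diag(pr$sdev[seq_len(k)], k, k)
    if (rotate && k > 1) {
        L <- .varimaxBest(L0)
    } else L <- L0
    dimnames(L) <- list(colnames(X), paste0("F", seq_len(k)))
    ## regression-method factor scores for the (rotated) loadings
    B <- L %*% solve(crossprod(L))
    S <- Z %*% B
    z0 <- (0 - mu) / sdv
    s0 <- drop(z0 %*% B)
    apcs <- sweep(S, 2, s0)
    colnames(apcs) <- colnames(L)
    fitOne <- function(y) {
        df <- data.frame(y = y, apcs)
        fit <- stats::lm(y ~ ., data = df)
        b <- stats::coef(fit)[-1]
        contrib <- 100 * colMeans(sweep(apcs, 2, b, "*")) / mean(fit$fitted.values)
        list(fit = fit, contrib = contrib,
             r2 = summary(fit)$r.squared)
    }
    if (response == "total") {
        res <- fitOne(rowSums(X))
        contributions <- res$contrib
        r2 <- res$r2
        model <- res$fit
        unexplained <- 100 - sum(contributions)
    } else {
        per <- lapply(seq_len(ncol(X)), function(j) fitOne(X[, j]))
        contributions <- t(vapply(per, function(r) r$contrib, numeric(k)))
        rownames(contributions) <- colnames(X)
        r2 <- vapply(per, function(r) r$r2, numeric(1))
        names(r2) <- colnames(X)
        model <- lapply(per, function(r) r$fit)
        unexplained <- 100 - rowSums(contributions)
    }
    list(loadings = L, unrotated = L0, scores = S, apcs = apcs,
         contributions = contributions, unexplained = unexplained,
         r2 = r2, model = model)
}

## Varimax with deterministic random restarts. stats::varimax started at
## the unrotated solution can stall at a saddle when loadings are highly
## symmetric; restarting from several random orthogonal rotations and
## keeping the best criterion value avoids that.
.varimaxBest <- function(L, nStarts = 12) {
    crit <- function(M) sum(apply(M^2, 2, stats::var))
    k <- ncol(L)
    ## exact pairwise-angle coordinate ascent; stats::varimax's fixed-point
    ## iteration can stop short of the optimum, so polish each candidate
    refine <- function(M) {
        if (k < 2) return(M)
        repeat {
            gain <- 0
            for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
                pairCrit <- function(t) {
                    a <- cos(t) * M[, i] + sin(t) * M[, j]
                    b <- -sin(t) * M[, i] + cos(t) * M[, j]
                    stats::var(a^2) + stats::var(b^2)
                }
                base <- pairCrit(0)
                opt <- stats::optimize(pairCrit, c(-pi / 4, pi / 4),
                                       maximum = TRUE, tol = 1e-10)
                if (opt$objective > base + 1e-12) {
                    t <- opt$maximum
                    a <- cos(t) * M[, i] + sin(t) * M[, j]
                    b <- -sin(t) * M[, i] + cos(t) * M[, j]
                    M[, i] <- a; M[, j] <- b
                    gain <- gain + opt$objective - base
                }
            }
            if (gain < 1e-12) break
        }
        M
    }
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(19)
    best <- NULL
    for (s in seq_len(nStarts)) {
        Q <- if (s == 1) diag(k)
             else qr.Q(qr(matrix(stats::rnorm(k * k), k)))
        rot <- tryCatch(stats::varimax(L %*% Q, normalize = FALSE,
                                       eps = 1e-10),
                        error = function(e) NULL)
        if (is.null(rot)) next
        cand <- refine(L %*% Q %*% rot$rotmat)
        if (is.null(best) || crit(cand) > crit(best)) best <- cand
    }
    best
}

#' Dominant factor per parameter
#'
#' Convenience cross-validation view: for each parameter, the factor with
#' the largest share, from either a PMF contribution matrix
#' (\code{\link{factorContributions}}) or APCS-MLR rotated loadings
#' (largest absolute loading).
#'
#' @param contrib matrix: factors x parameters (PMF percentages) or
#'   parameters x factors (APCS loadings).
#' @param byRow logical; \code{TRUE} when factors are rows.
#' @return named integer vector: dominant factor index per parameter.
#' @export
dominantFactor <- function(contrib, byRow = TRUE) {
    M <- if (byRow) t(contrib) else contrib
    idx <- apply(abs(M), 1, which.max)
    names(idx) <- rownames(M)
    idx
}
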