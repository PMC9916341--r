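#' Measurement uncertainty matrix for receptor modelling
#'
#' EPA-style per-cell uncertainties: below or at the detection limit,
#' \code{u = (5/6) * MDL}; above it, \code{u = sqrt(MDL^2 +
#' (errorFraction * C)^2)}. The default error fraction is 3.5%.
#'
#' @param X nonnegative data matrix, samples x parameters (named columns).
#' @param mdl named vector of method detection limits per parameter (>= 0);
#'   parameters absent from \code{mdl} get MDL = 0.
#' @param errorFraction relative measurement error, in (0, 1).
#' @return matrix U of the same shape as \code{X}.
#' @examples
#' buildUncertainty(matrix(0.05, 1, 1, dimnames = list(NULL, "Cr")),
#'                  c(Cr = 0.1))           # 5/6 * 0.1
#' @export
buildUncertainty <- function(X, mdl, errorFraction = 0.035) {
    X <- as.matrix(X)
    if (any(!is.finite(X)) || any(X < 0))
        stop("X must be finite and nonnegative")
    if (errorFraction <= 0 || errorFraction >= 1)
        stop("errorFraction must be in (0, 1)")
    if (any(mdl < 0)) stop("MDL must be >= 0")
    m <- rep(0, ncol(X))
    names(m) <- colnames(X)
    if (!is.null(names(mdl)) && !is.null(colnames(X))) {
        hit <- intersect(names(mdl), colnames(X))
        m[hit] <- mdl[hit]
    } else {
        m[] <- rep_len(mdl, ncol(X))
    }
    M <- matrix(m, nrow(X), ncol(X), byrow = TRUE)
    U <- sqrt(M^2 + (errorFraction * X)^2)
    below <- X <= M
    U[below] <- (5 / 6) * M[below]
    U
}

#' Per-parameter signal-to-noise ratio
#'
#' EPA PMF 5.0 convention: \code{S/N_j = mean_i(d_ij)} with
#' \code{d_ij = (x_ij - u_ij) / u_ij} when \code{x_ij > u_ij}, else 0.
#'
#' @param X data matrix, samples x parameters.
#' @param U uncertainty matrix, same shape, strictly positive.
#' @return named numeric vector of S/N per parameter.
#' @export
signalToNoise <- function(X, U) {
    X <- as.matrix(X); U <- as.matrix(U)
    if (!identical(dim(X), dim(U))) stop("X and U shapes differ")
    if (any(U <= 0)) stop("uncertainties must be > 0")
    D <- (X - U) / U
    D[X <= U] <- 0
    colMeans(D)
}

#' Uncertainty-weighted factorization objective
#'
#' \code{Q = sum(((X - G F) / U)^2)}. In robust mode each scaled residual
#' \code{r = e/u} with \code{|r| > 4} is downweighted by \code{4 u / |e|},
#' capping its contribution at 16.
#'
#' @param X,U data and uncertainty matrices (samples x parameters).
#' @param G contributions (samples x factors).
#' @param F profiles (factors x parameters).
#' @param robust logical; cap scaled residuals at 4.
#' @return the scalar objective Q.
#' @export
pmfObjective <- function(X, U, G, F, robust = FALSE) {
    R <- (X - G %*% F) / U
    if (robust) {
        R2 <- R^2
        sum(pmin(R2, 16))
    } else sum(R^2)
}

#' Fit a positive matrix factorization receptor model
#'
#' Factorizes \code{X ~ G F} with \code{G >= 0}, \code{F >= 0} by
#' minimizing the uncertainty-weighted squared residual objective Q
#' (\code{\link{pmfObjective}}) with multiplicative updates on the weighted
#' Frobenius loss (weights \code{1/U^2}), which make Q nonincreasing at
#' every iteration. The best of \code{nStarts} random nonnegative
#' initializations is kept. Convergence: relative change in Q below
#' \code{tol} over a 20-iteration window; non-convergence within
#' \code{maxIter} iterations flags the result instead of failing.
#'
#' @param X nonnegative data matrix, samples x parameters.
#' @param U positive uncertainty matrix, same shape.
#' @param p number of factors, \code{p < min(dim(X))}.
#' @param nStarts random starts (base runs), >= 1.
#' @param seed integer seed making the fit reproducible.
#' @param maxIter maximum iterations per start.
#' @param tol relative Q-change convergence tolerance.
#' @return a \linkS4class{PMFFit}.
#' @export
fitPMF <- function(X, U, p, nStarts = 20, seed = 1, maxIter = 5000,
                   tol = 1e-8) {
    X <- as.matrix(X); U <- as.matrix(U)
    if (!identical(dim(X), dim(U))) stop("X and U shapes differ")
    if (any(X < 0)) stop("X must be nonnegative")
    if (any(U <= 0)) stop("uncertainties must be > 0")
    if (p >= min(dim(X))) stop("p must be < min(n, m)")
    if (nStarts < 1) stop("nStarts must be >= 1")
    W <- 1 / U^2
    WX <- W * X
    eps <- .Machine$double.eps
    scale0 <- sqrt(mean(X) / p)
    best <- NULL
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(seed)
    for (s in seq_len(nStarts)) {
        G <- matrix(stats::runif(nrow(X) * p), nrow(X), p) * scale0 + eps
        F <- matrix(stats::runif(p * ncol(X)), p, ncol(X)) * scale0 + eps
        qPath <- numeric(0)
        converged <- FALSE
        it <- 0L
        while (it < maxIter) {
            it <- it + 1L
            GF <- G %*% F
            G <- G * (WX %*% t(F)) / ((W * GF) %*% t(F) + eps)
            GF <- G %*% F
            F <- F * (t(G) %*% WX) / (t(G) %*% (W * GF) + eps)
            q <- sum(W * (X - G %*% F)^2)
            qPath <- c(qPath, q)
            if (it >= 20) {
                qOld <- qPath[it - 19L]
                if ((qOld - q) <= tol * max(qOld, eps)) {
                    converged <- TRUE
                    break
                }
            }
        }
        if (is.null(best) || q < best$q)
            best <- list(G = G, F = F, q = q, qPath = qPath,
                         converged = converged, nIter = it)
    }
    if (!best$converged)
        warning("PMF did not converge within ", maxIter, " iterations")
    methods::new("PMFFit", X = X, U = U, G = best$G, F = best$F,
                 qTrue = best$q,
                 qRobust = pmfObjective(X, U, best$G, best$F, robust = TRUE),
                 converged = best$converged, nIter = best$nIter,
                 nStarts = as.integer(nStarts), seed = as.integer(seed),
                 qPath = best$qPath)
}

#' Q versus number-of-factors scan
#'
#' Refits the model for each candidate factor count and reports Q(true),
#' Q(robust) and their ratio, mimicking the usual 3-to-5-factor screening.
#' No automatic selection is made.
#'
#' @inheritParams fitPMF
#' @param pValues candidate factor counts.
#' @return data.frame with \code{p}, \code{qTrue}, \code{qRobust},
#'   \code{ratio}, \code{converged}.
#' @export
scanFactors <- function(X, U, pValues = 3:5, nStarts = 20, seed = 1,
                        maxIter = 5000) {
    res <- lapply(pValues, function(p) {
        fit <- fitPMF(X, U, p, nStarts = nStarts, seed = seed,
                      maxIter = maxIter)
        data.frame(p = p, qTrue = fit@qTrue, qRobust = fit@qRobust,
                   ratio = fit@qTrue / fit@qRobust,
                   converged = fit@converged)
    })
    do.call(rbind, res)
}

#' Per-parameter percent contribution of each factor
#'
#' For parameter j, the share of factor k is
#' \code{sum_i g_ik f_kj / sum_ik g_ik f_kj * 100}; shares sum to 100 per
#' parameter.
#'
#' @param fit a \linkS4class{PMFFit}.
#' @return matrix, factors x parameters, of percentages.
#' @export
factorContributions <- function(fit) {
    gtot <- colSums(fit@G)                       # sum_i g_ik
    M <- gtot * fit@F                            # M_kj = sum_i g_ik f_kj
    tot <- colSums(M)
    if (any(tot <= 0)) stop("all-zero reconstruction for some parameter")
    sweep(M, 2, tot, "/") * 100
}

#' Per-parameter coefficient of determination of the reconstruction
#'
#' Squared correlation between observed and reconstructed concentrations.
#'
#' @param fit a \linkS4class{PMFFit}.
#' @return named numeric vector of R-squared per parameter.
#' @export
reconstructionR2 <- function(fit) {
    Xhat <- fit@G %*% fit@F
    r2 <- vapply(seq_len(ncol(fit@X)), function(j) {
        stats::cor(fit@X[, j], Xhat[, j])^2
    }, numeric(1))
    names(r2) <- colnames(fit@X)
    r2
}

#' Cosine similarity between two vectors or matrix columns
#' @param a,b numeric vectors of equal length.
#' @return cosine of the angle between \code{a} and \code{b}.
#' @export
cosineSimilarity <- function(a, b) {
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match recovered factors to reference factors
#'
#' Exhaustive assignment (factor counts here are small) maximizing the
#' total cosine similarity between recovered and reference profile rows.
#'
#' @param Fhat recovered profile matrix, factors x parameters.
#' @param Fref reference profile matrix, same shape.
#' @return list with \code{perm} (index into \code{Fhat} rows for each
#'   reference row) and \code{similarity} (matched cosine per reference
#'   factor).
#' @export
matchFactors <- function(Fhat, Fref) {
    p <- nrow(Fref)
    if (nrow(Fhat) != p) stop("factor counts differ")
    S <- matrix(0, p, p)
    for (i in seq_len(p)) for (j in seq_len(p))
        S[i, j] <- cosineSimilarity(Fref[i, ], Fhat[j, ])
    perms <- .permutations(p)
    score <- apply(perms, 1, function(pr) sum(S[cbind(seq_len(p), pr)]))
    bestPerm <- as.integer(unname(perms[which.max(score), ]))
    list(perm = bestPerm,
         similarity = S[cbind(seq_len(p), bestPerm)])
}

.permutations <- function(n) {
    if (n == 1) return(matrix(1, 1, 1))
    sub <- .permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, sub + (sub >= k))
    }))
}
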