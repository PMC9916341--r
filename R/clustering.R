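#' Hierarchical agglomerative cluster analysis (Ward)
#'
#' Euclidean distance on (by default) z-scored variables, Ward linkage
#' (\code{hclust} method \code{"ward.D2"}), tree cut at \code{k} clusters.
#' Centroids are reported in original units; the variance decomposition
#' (within- versus between-cluster percent of total sum of squares) is
#' computed in the clustering space.
#'
#' @param x a \linkS4class{WaterChemSet} or a samples x variables matrix.
#' @param params variables to cluster on (rows of the assay); default all.
#' @param k number of clusters.
#' @param standardize z-score variables before the distance (default TRUE;
#'   mixed units make this necessary).
#' @return list of class \code{"haca"}: \code{tree} (hclust), \code{labels}
#'   (cluster per sample), \code{counts}, \code{centroids} (original
#'   units, clusters x variables), \code{withinPct}, \code{betweenPct},
#'   \code{totalSS}.
#' @export
haca <- function(x, params = NULL, k = 3, standardize = TRUE) {
    M <- if (methods::is(x, "WaterChemSet")) {
        if (is.null(params)) params <- rownames(x)
        t(concMatrix(x)[params, , drop = FALSE])
    } else as.matrix(x)
    if (anyNA(M)) stop("clustering requires complete measurements")
    if (k < 1 || k > nrow(M)) stop("need n >= k >= 1")
    Z <- if (standardize) {
        sdv <- apply(M, 2, stats::sd)
        if (any(sdv == 0))
            stop("degenerate scale: constant variable under standardization")
        scale(M)
    } else M
    tree <- stats::hclust(stats::dist(Z), method = "ward.D2")
    labels <- stats::cutree(tree, k = k)
    centroids <- apply(M, 2, function(col) tapply(col, labels, mean))
    if (k == 1) centroids <- matrix(centroids, nrow = 1,
                                    dimnames = list("1", colnames(M)))
    grand <- colMeans(Z)
    totalSS <- sum(sweep(Z, 2, grand)^2)
    withinSS <- sum(vapply(unique(labels), function(cl) {
        sub <- Z[labels == cl, , drop = FALSE]
        sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
    res <- list(tree = tree, labels = labels,
                counts = as.integer(table(labels)),
                centroids = centroids,
                withinPct = 100 * withinSS / totalSS,
                betweenPct = 100 * (totalSS - withinSS) / totalSS,
                totalSS = totalSS, standardized = standardize)
    class(res) <- "haca"
    res
}

#' @export
print.haca <- function(x, ...) {
    cat("Ward hierarchical clustering:", length(x$labels), "samples,",
        nrow(x$centroids), "clusters\n")
    cat(sprintf("  within-cluster %.2f%% / between-cluster %.2f%% of total SS\n",
                x$withinPct, x$betweenPct))
    cat("  sizes:", paste(x$counts, collapse = ", "), "\n")
    invisible(x)
}

#' Pollution-severity ordering of three clusters
#'
#' Orders the k = 3 clusters by the centroid sum of metal single-factor
#' ratios (centroid concentration over guideline limit) and labels them
#' least / moderately / severely polluted. Ties are broken lexicographically
#' by cluster id and flagged.
#'
#' @param result a \code{\link{haca}} result with 3 clusters.
#' @param metals metal set for the burden (default Cr, Ni, Mn).
#' @param standards named guideline limits (default
#'   \code{\link{whoStandards}()}).
#' @return data.frame with \code{cluster}, \code{burden}, \code{severity},
#'   \code{n}, \code{share_pct}; attribute \code{"tie"} flags equal
#'   burdens.
#' @export
severityRanking <- function(result, metals = c("Cr", "Ni", "Mn"),
                            standards = whoStandards()) {
    cent <- result$centroids
    if (nrow(cent) != 3) stop("severity ranking requires k = 3 clusters")
    metals <- intersect(metals, colnames(cent))
    if (!length(metals)) stop("no metal centroids available")
    burden <- rowSums(sweep(cent[, metals, drop = FALSE], 2,
                            standards[metals], "/"))
    tie <- anyDuplicated(burden) > 0
    if (tie) warning("tied cluster burdens; lexicographic tie-break applied")
    ord <- order(burden, as.integer(names(burden)))
    severity <- character(3)
    severity[ord] <- c("least", "moderately", "severely")
    n <- result$counts
    data.frame(cluster = as.integer(names(burden)), burden = burden,
               severity = severity, n = n,
               share_pct = 100 * n / sum(n),
               row.names = NULL) -> out
    attr(out, "tie") <- tie
    out
}

#' Export a dendrogram as nested text plus a merge-height table
#'
#' @param tree an \code{hclust} object.
#' @return list with \code{newick} (Newick-like nested string, heights as
#'   branch annotations) and \code{merges} (data.frame step/height).
#' @export
dendrogramExport <- function(tree) {
    lab <- tree$labels
    if (is.null(lab)) lab <- as.character(seq_len(nrow(tree$merge) + 1))
    node <- function(i) {
        if (i < 0) return(lab[-i])
        paste0("(", node(tree$merge[i, 1]), ",", node(tree$merge[i, 2]),
               "):", format(tree$height[i], digits = 6))
    }
    root <- nrow(tree$merge)
    rootStr <- paste0("(", node(tree$merge[root, 1]), ",",
                      node(tree$merge[root, 2]), ")")
    list(newick = paste0(rootStr, ";"),
         merges = data.frame(step = seq_along(tree$height),
                             height = tree$height))
}
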