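#' Single-factor pollution ratio
#'
#' Ratio of a measured concentration to its guideline limit, C_i / S_i.
#'
#' @param conc concentration(s), same units as the standard.
#' @param standard guideline limit S_i > 0, or a named standards vector as
#'   from \code{\link{whoStandards}} combined with \code{param}.
#' @param param optional parameter name used to index a named standards
#'   vector.
#' @return C/S ratio(s).
#' @examples
#' singleFactor(1500, whoStandards(), "EC")  # 3.75
#' singleFactor(6.0, 0.05)                   # 120
#' @export
singleFactor <- function(conc, standard, param = NULL) {
    s <- if (!is.null(param)) {
        if (!param %in% names(standard)) stop("no standard for ", param)
        standard[[param]]
    } else standard
    if (any(s <= 0)) stop("standard limit must be > 0")
    conc / s
}

#' Nemerow composite pollution index
#'
#' \code{NPI = sqrt((mean(C/S)^2 + max(C/S)^2) / 2)} over a parameter set.
#' pH is excluded by default because the ratio form is ill-defined for a
#' two-sided parameter; pass \code{phStandard} to fold it in as C/phStandard.
#'
#' @param x a \linkS4class{WaterChemSet} or a named concentration vector.
#' @param standards named limits, default \code{\link{whoStandards}()}.
#' @param params parameters entering the composite; default: all parameters
#'   present in both the data and the standards.
#' @param phStandard optional denominator for pH (e.g. 7.8); \code{NULL}
#'   (default) excludes pH.
#' @return per-sample data.frame with \code{npi}, \code{mean_ratio},
#'   \code{max_ratio}.
#' @examples
#' nemerowIndex(c(Cr = 0.05, Ni = 9))  # ratios 1 and 3 -> 2.5495
#' @export
nemerowIndex <- function(x, standards = whoStandards(), params = NULL,
                         phStandard = NULL) {
    conc <- if (methods::is(x, "WaterChemSet")) concMatrix(x)
            else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
    std <- standards
    if (!is.null(phStandard)) std["pH"] <- phStandard else std <- std[names(std) != "pH"]
    if (is.null(params)) params <- intersect(rownames(conc), names(std))
    params <- intersect(params, names(std))
    if (!length(params)) stop("empty parameter set for the Nemerow index")
    ratios <- conc[params, , drop = FALSE] / std[params]
    res <- data.frame(
        sample_id = colnames(conc),
        mean_ratio = apply(ratios, 2, mean, na.rm = TRUE),
        max_ratio = apply(ratios, 2, max, na.rm = TRUE))
    res$npi <- sqrt((res$mean_ratio^2 + res$max_ratio^2) / 2)
    rownames(res) <- NULL
    res
}

#' Guideline exceedance percentages
#'
#' Share of samples with C > S for every parameter, per group and overall.
#'
#' @param x a \linkS4class{WaterChemSet}.
#' @param standards named limits, default \code{\link{whoStandards}()}.
#' @return data.frame with columns \code{parameter}, \code{group}
#'   (including \code{"overall"}), \code{n}, \code{n_exceeding},
#'   \code{percent}.
#' @export
exceedanceTable <- function(x, standards = whoStandards()) {
    conc <- concMatrix(x)
    params <- intersect(rownames(conc), names(standards))
    if (!ncol(conc)) stop("no samples")
    grp <- as.character(sampleGroup(x))
    groups <- c(unique(grp), "overall")
    res <- do.call(rbind, lapply(params, function(p) {
        do.call(rbind, lapply(groups, function(g) {
            v <- if (g == "overall") conc[p, ] else conc[p, grp == g]
            v <- v[!is.na(v)]
            data.frame(parameter = p, group = g, n = length(v),
                       n_exceeding = sum(v > standards[[p]]),
                       percent = if (length(v))
                           100 * sum(v > standards[[p]]) / length(v)
                       else NA_real_)
        }))
    }))
    rownames(res) <- NULL
    res
}
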