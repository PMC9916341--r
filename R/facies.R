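#' Gibbs diagram coordinates
#'
#' The two classical mechanism ratios plotted against log10 TDS:
#' \code{x1 = Na/(Na+Ca)}, \code{x2 = Cl/(Cl+HCO3)}, \code{y = log10(TDS)}.
#' Ratios are computed on mass concentrations (mg/L) by default, matching
#' the usual presentation; set \code{units = "meq"} for equivalent-based
#' ratios.
#'
#' @param x a \linkS4class{WaterChemSet} or named concentration vector with
#'   Na, Ca, Cl, HCO3 and TDS in mg/L.
#' @param units \code{"mg"} (default) or \code{"meq"}.
#' @return data.frame with \code{sample_id}, \code{gibbs_x1},
#'   \code{gibbs_x2}, \code{gibbs_y}.
#' @export
gibbsCoords <- function(x, units = c("mg", "meq")) {
    units <- match.arg(units)
    conc <- if (methods::is(x, "WaterChemSet")) concMatrix(x)
            else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
    need <- c("Na", "Ca", "Cl", "HCO3", "TDS")
    if (!all(need %in% rownames(conc)))
        stop("need Na, Ca, Cl, HCO3 and TDS")
    val <- function(p) {
        v <- conc[p, ]
        if (units == "meq" && p != "TDS") v <- toMeq(v, p)
        v
    }
    na <- val("Na"); ca <- val("Ca"); cl <- val("Cl"); hco3 <- val("HCO3")
    tds <- conc["TDS", ]
    if (any(na + ca <= 0 | cl + hco3 <= 0 | tds <= 0, na.rm = TRUE))
        stop("undefined Gibbs coordinate: zero denominator or nonpositive TDS")
    data.frame(sample_id = colnames(conc),
               gibbs_x1 = na / (na + ca),
               gibbs_x2 = cl / (cl + hco3),
               gibbs_y = log10(tds), row.names = NULL)
}

#' Chadha diagram coordinates and water-type classification
#'
#' Coordinates in milliequivalent-percent: on the cation panel
#' \code{chadha_x = ((Ca+Mg) - (Na+K)) / (total cation meq) * 100}, on the
#' anion panel \code{chadha_y = (HCO3 - (Cl+SO4)) / (total anion meq) * 100}.
#' The water type follows from the sign quadrant:
#' (+,+) Ca-HCO3; (-,+) Na-HCO3; (-,-) Na-Cl; (+,-) Ca-Mg-Cl.
#' A coordinate exactly 0 is assigned to the positive side and flagged
#' (\code{boundary = TRUE}).
#'
#' @param x a \linkS4class{WaterChemSet} or named mg/L concentration vector
#'   with Na, K, Ca, Mg, HCO3, Cl, SO4.
#' @return data.frame with \code{sample_id}, \code{chadha_x},
#'   \code{chadha_y}, \code{water_type}, \code{boundary}.
#' @export
chadhaClassify <- function(x) {
    conc <- if (methods::is(x, "WaterChemSet")) concMatrix(x)
            else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
    need <- c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "SO4")
    if (!all(need %in% rownames(conc)))
        stop("need the six major ions Na, K, Ca, Mg, HCO3, Cl, SO4")
    meq <- vapply(need, function(p) toMeq(conc[p, ], p),
                  numeric(ncol(conc)))
    meq <- matrix(meq, ncol = length(need),
                  dimnames = list(colnames(conc), need))
    catTot <- rowSums(meq[, c("Na", "K", "Ca", "Mg"), drop = FALSE])
    anTot <- rowSums(meq[, c("HCO3", "Cl", "SO4"), drop = FALSE])
    cx <- 100 * ((meq[, "Ca"] + meq[, "Mg"]) -
                 (meq[, "Na"] + meq[, "K"])) / catTot
    cy <- 100 * (meq[, "HCO3"] -
                 (meq[, "Cl"] + meq[, "SO4"])) / anTot
    type <- ifelse(cx >= 0,
                   ifelse(cy >= 0, "Ca-HCO3", "Ca-Mg-Cl"),
                   ifelse(cy >= 0, "Na-HCO3", "Na-Cl"))
    data.frame(sample_id = colnames(conc), chadha_x = cx, chadha_y = cy,
               water_type = factor(type, levels = .WATER_TYPES),
               boundary = cx == 0 | cy == 0, row.names = NULL)
}

.WATER_TYPES <- c("Ca-HCO3", "Na-HCO3", "Na-Cl", "Ca-Mg-Cl")

#' Water-type frequency tally
#'
#' Percentage of samples in each Chadha water type, overall and (for a
#' \linkS4class{WaterChemSet}) per group.
#'
#' @param x a \linkS4class{WaterChemSet}, or the data.frame returned by
#'   \code{\link{chadhaClassify}}.
#' @return data.frame with \code{group}, \code{water_type}, \code{n},
#'   \code{percent}; percentages sum to 100 within each group.
#' @export
faciesTally <- function(x) {
    if (methods::is(x, "WaterChemSet")) {
        cls <- chadhaClassify(x)
        grp <- as.character(sampleGroup(x))
    } else {
        cls <- x
        grp <- rep("overall", nrow(cls))
    }
    groups <- c(unique(grp), if (!"overall" %in% grp) "overall")
    res <- do.call(rbind, lapply(groups, function(g) {
        sel <- if (g == "overall") rep(TRUE, nrow(cls)) else grp == g
        tab <- table(cls$water_type[sel])
        data.frame(group = g, water_type = names(tab),
                   n = as.integer(tab),
                   percent = 100 * as.integer(tab) / sum(sel))
    }))
    rownames(res) <- NULL
    res
}
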