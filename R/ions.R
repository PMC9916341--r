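#' Registered ion properties
#'
#' Molar masses (g/mol) and formula charges of the measured ions, used for
#' milliequivalent conversion, the charge-balance QC and Chadha coordinates.
#' Bundled as a versioned table (attribute \code{"version"}) so the
#' conversion constants are data, not scattered magic numbers.
#'
#' @return data.frame with columns \code{parameter}, \code{molar_mass},
#'   \code{charge}.
#' @export
ionTable <- function() {
    tab <- data.frame(
        parameter  = c("Na", "K", "Ca", "Mg",
                       "HCO3", "Cl", "SO4", "NO3", "PO4"),
        molar_mass = c(22.99, 39.098, 40.08, 24.305,
                       61.017, 35.453, 96.06, 62.004, 94.971),
        charge     = c(1L, 1L, 2L, 2L, -1L, -1L, -2L, -1L, -3L),
        stringsAsFactors = FALSE)
    attr(tab, "version") <- "1.0"
    tab
}

.BALANCE_CATIONS <- c("Na", "K", "Ca", "Mg")
.BALANCE_ANIONS  <- c("HCO3", "Cl", "SO4", "NO3", "PO4")

.ionSpec <- function(ion) {
    tab <- ionTable()
    i <- match(ion, tab$parameter)
    if (any(is.na(i)))
        stop("unknown ion(s): ", paste(ion[is.na(i)], collapse = ", "))
    tab[i, , drop = FALSE]
}

#' Convert a concentration from mg/L to meq/L
#'
#' \code{meq/L = mg/L * |charge| / molar mass}.
#'
#' @param conc nonnegative concentration(s) in mg/L.
#' @param ion ion name(s), recycled against \code{conc}; must be registered
#'   in \code{\link{ionTable}}.
#' @return meq/L, same length as \code{conc}.
#' @examples
#' toMeq(230, "Na")   # 10.004 meq/L
#' toMeq(40.08, "Ca") # 2 meq/L
#' @export
toMeq <- function(conc, ion) {
    if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
    spec <- .ionSpec(ion)
    conc * abs(spec$charge) / spec$molar_mass
}

#' Ion charge balance error (ICBE)
#'
#' Signed percent mismatch between total cation and total anion charge,
#' \code{100 * (sum cations - sum anions) / (sum cations + sum anions)} with
#' both sums in meq/L. |ICBE| <= 5 is the conventional QC acceptance band.
#' Cations are Na, K, Ca, Mg; anions HCO3, Cl, SO4, NO3, PO4 (configurable:
#' whether NO3 and PO4 enter the balance is a survey-level choice). Missing
#' concentrations are treated as not measured and skipped with a warning.
#'
#' @param x a \linkS4class{WaterChemSet}, or a named numeric vector of
#'   concentrations in mg/L.
#' @param cations,anions ion sets entering the balance.
#' @return data.frame with columns \code{sample_id}, \code{cations_meq},
#'   \code{anions_meq}, \code{icbe}, \code{acceptable} (|ICBE| <= 5).
#' @examples
#' icbe(c(Na = 230, Cl = 354.6))   # ~0: 10 meq/L on each side
#' @export
icbe <- function(x, cations = .BALANCE_CATIONS, anions = .BALANCE_ANIONS) {
    conc <- if (methods::is(x, "WaterChemSet")) concMatrix(x)
            else matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
    cat_in <- intersect(cations, rownames(conc))
    an_in <- intersect(anions, rownames(conc))
    if (!length(cat_in) || !length(an_in))
        stop("need at least one measured cation and one anion")
    if (anyNA(conc[c(cat_in, an_in), ]))
        warning("missing ion concentrations excluded from the charge balance")
    meqSum <- function(ions, j) {
        v <- conc[ions, j]
        ok <- !is.na(v)
        if (!any(ok)) return(NA_real_)
        sum(toMeq(v[ok], ions[ok]))
    }
    res <- do.call(rbind, lapply(seq_len(ncol(conc)), function(j) {
        cs <- meqSum(cat_in, j)
        as <- meqSum(an_in, j)
        if (isTRUE(cs + as == 0))
            stop("undefined balance: cation and anion sums both zero")
        data.frame(sample_id = colnames(conc)[j],
                   cations_meq = cs, anions_meq = as,
                   icbe = 100 * (cs - as) / (cs + as))
    }))
    res$acceptable <- abs(res$icbe) <= 5
    rownames(res) <- NULL
    res
}

#' WHO guideline limits
#'
#' Default standards table: the WHO drinking-water guideline values used for
#' the pollution indices and exceedance screening, in the measurement units
#' of each parameter. pH is two-sided (6.5--9.2) and therefore excluded; see
#' \code{\link{nemerow}} for how it can be optionally folded in.
#'
#' @return named numeric vector of limits S_i > 0.
#' @export
whoStandards <- function() {
    c(EC = 400, Turbidity = 5.0, TDS = 1000,
      Na = 200, K = 12, Mg = 50, Ca = 100,
      PO4 = 0.1, NO3 = 50, HCO3 = 500, Cl = 250, SO4 = 500,
      Cr = 0.05, Ni = 3.0, Mn = 0.5)
}
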