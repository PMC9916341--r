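#' Cohort exposure profiles
#'
#' Drinking-water ingestion parameters per cohort: ingestion rate IR (L/day;
#' child 2, male 2.5, female 3), body weight BW (kg; child 18, male 65,
#' female 62), exposure frequency EF (days/year), exposure duration ED
#' (years) and averaging time AT (days).
#'
#' Two conventions are bundled. \code{"lifetime"} (default) sets ED = 70 y,
#' EF = 365 d/y, AT = 25550 d, so EF*ED/AT = 1 and CDI = C*IR/BW; this is
#' the convention that reproduces the published risk tables exactly.
#' \code{"printed"} carries the constants as often printed alongside the
#' intake equation (ED = 350 d read as a daily count, EF = 365 d/y,
#' AT = 70*365 d), which yields values about 5x larger; it is retained so
#' the discrepancy between the equation text and the tabulated results can
#' be inspected.
#'
#' @param convention \code{"lifetime"} or \code{"printed"}.
#' @return data.frame with rows child, male, female and columns
#'   \code{cohort}, \code{IR}, \code{BW}, \code{EF}, \code{ED}, \code{AT},
#'   \code{intake_factor} (= IR*EF*ED/(BW*AT), 1/(kg day/L)).
#' @export
exposureProfiles <- function(convention = c("lifetime", "printed")) {
    convention <- match.arg(convention)
    prof <- data.frame(
        cohort = c("child", "male", "female"),
        IR = c(2, 2.5, 3),
        BW = c(18, 65, 62))
    if (convention == "lifetime") {
        prof$EF <- 365; prof$ED <- 70; prof$AT <- 70 * 365
        tfac <- prof$EF * prof$ED / prof$AT      # = 1
    } else {
        prof$EF <- 365; prof$ED <- 350; prof$AT <- 70 * 365
        tfac <- prof$ED * prof$EF / prof$AT      # ~ 5
    }
    prof$intake_factor <- prof$IR * tfac / prof$BW
    attr(prof, "convention") <- convention
    rownames(prof) <- prof$cohort
    prof
}

#' Oral toxicity constants
#'
#' Reference doses RfD (mg/kg/day; Cr 1.5, Ni 0.02, Mn 0.14 as fixed by the
#' internal CDI/HQ ratios of the published risk table) and cancer slope
#' factors CSF ((mg/kg/day)^-1; Cr 0.5, Ni 0.91; Mn is not treated as
#' carcinogenic).
#'
#' @return data.frame with columns \code{metal}, \code{RfD}, \code{CSF}.
#' @export
defaultToxicity <- function() {
    data.frame(metal = c("Cr", "Ni", "Mn"),
               RfD = c(1.5, 0.02, 0.14),
               CSF = c(0.5, 0.91, NA_real_),
               row.names = c("Cr", "Ni", "Mn"))
}

#' Chronic daily intake via drinking-water ingestion
#'
#' \code{CDI = C * IR * EF * ED / (BW * AT)} in mg/kg/day. Under the default
#' lifetime convention EF*ED/AT = 1, so CDI = C * IR / BW.
#'
#' @param conc concentration(s) in mg/L, >= 0.
#' @param cohort \code{"child"}, \code{"male"} or \code{"female"}.
#' @param profiles profile table from \code{\link{exposureProfiles}}.
#' @return CDI in mg/kg/day.
#' @examples
#' cdi(4.5, "child")  # 0.5
#' @export
cdi <- function(conc, cohort, profiles = exposureProfiles()) {
    if (any(conc < 0, na.rm = TRUE)) stop("concentration must be >= 0")
    p <- profiles[match(cohort, profiles$cohort), ]
    if (anyNA(p$cohort)) stop("unknown cohort: ", cohort)
    if (any(p$BW <= 0)) stop("nonpositive body weight in profile")
    conc * p$intake_factor
}

#' Hazard quotient
#'
#' \code{HQ = CDI / RfD}; HQ > 1 flags noncarcinogenic concern.
#'
#' @param cdiValue CDI in mg/kg/day.
#' @param metal metal name used to look up RfD, or \code{NULL} if
#'   \code{rfd} is given directly.
#' @param rfd reference dose override (mg/kg/day).
#' @param toxicity toxicity table from \code{\link{defaultToxicity}}.
#' @return unitless hazard quotient.
#' @export
hazardQuotient <- function(cdiValue, metal = NULL, rfd = NULL,
                           toxicity = defaultToxicity()) {
    if (is.null(rfd)) {
        if (is.null(metal) || !all(metal %in% rownames(toxicity)))
            stop("no RfD available for: ",
                 paste(setdiff(metal, rownames(toxicity)), collapse = ", "))
        rfd <- toxicity[metal, "RfD"]
    }
    if (any(is.na(rfd)) || any(rfd <= 0)) stop("RfD must be > 0")
    cdiValue / rfd
}

#' Hazard index: sum of hazard quotients over metals
#'
#' @param hq numeric vector of HQ values for one sample and cohort.
#' @return HI = sum(HQ).
#' @export
hazardIndex <- function(hq) {
    if (!length(hq)) stop("empty HQ set")
    sum(hq)
}

#' Incremental lifetime cancer risk
#'
#' \code{CR = CDI * CSF}, defined only for metals with a slope factor
#' (Cr, Ni). The conventional acceptable band is 1e-6 to 1e-4; values above
#' 1e-4 are considered intolerable.
#'
#' @inheritParams hazardQuotient
#' @param csf cancer slope factor override ((mg/kg/day)^-1).
#' @return unitless lifetime cancer risk.
#' @export
cancerRisk <- function(cdiValue, metal = NULL, csf = NULL,
                       toxicity = defaultToxicity()) {
    if (is.null(csf)) {
        if (is.null(metal) || !all(metal %in% rownames(toxicity)))
            stop("unknown metal for CSF lookup")
        csf <- toxicity[metal, "CSF"]
        if (any(is.na(csf)))
            stop("not carcinogenic (no CSF): ",
                 paste(metal[is.na(csf)], collapse = ", "))
    }
    cdiValue * csf
}

#' Total hazard index across metals
#'
#' Group-level sum of hazard quotients (noncarcinogenic mode) or cancer
#' risks (carcinogenic mode). Applied to group range endpoints it
#' reproduces the published THI rows.
#'
#' @param values per-metal HQ or CR values.
#' @param mode \code{"noncarcinogenic"} or \code{"carcinogenic"} (label
#'   only; both sum).
#' @return sum of \code{values}.
#' @export
totalHazardIndex <- function(values,
                             mode = c("noncarcinogenic", "carcinogenic")) {
    match.arg(mode)
    if (!length(values)) stop("empty input")
    sum(values)
}

#' Full deterministic health-risk chain
#'
#' Computes CDI, HQ and (for carcinogenic metals) CR for every sample,
#' metal and cohort, plus the per-sample hazard index HI.
#'
#' @param x a \linkS4class{WaterChemSet}.
#' @param metals metals to assess (default Cr, Ni, Mn).
#' @param profiles exposure profiles, see \code{\link{exposureProfiles}}.
#' @param toxicity toxicity constants, see \code{\link{defaultToxicity}}.
#' @return list with \code{perSample} (long data.frame: sample_id, group,
#'   cohort, metal, conc, cdi, hq, cr) and \code{hi} (sample_id, group,
#'   cohort, hi).
#' @export
healthRisk <- function(x, metals = c("Cr", "Ni", "Mn"),
                       profiles = exposureProfiles(),
                       toxicity = defaultToxicity()) {
    conc <- concMatrix(x)
    metals <- intersect(metals, rownames(conc))
    if (!length(metals)) stop("none of the requested metals are measured")
    grp <- as.character(sampleGroup(x))
    res <- do.call(rbind, lapply(profiles$cohort, function(co) {
        do.call(rbind, lapply(metals, function(m) {
            cv <- conc[m, ]
            d <- cdi(cv, co, profiles)
            data.frame(sample_id = colnames(conc), group = grp,
                       cohort = co, metal = m, conc = cv, cdi = d,
                       hq = hazardQuotient(d, m, toxicity = toxicity),
                       cr = if (is.na(toxicity[m, "CSF"])) NA_real_
                            else cancerRisk(d, m, toxicity = toxicity))
        }))
    }))
    rownames(res) <- NULL
    hi <- stats::aggregate(hq ~ sample_id + group + cohort, data = res, sum)
    names(hi)[names(hi) == "hq"] <- "hi"
    list(perSample = res, hi = hi)
}

#' Group-level risk summary with total hazard indices
#'
#' Range (min--max) and mean +/- sd of CDI, HQ and CR per group, cohort and
#' metal, in the layout of a published risk compilation, plus THI rows:
#' per group and cohort, the sum across metals of the per-metal minima,
#' maxima and means of HQ (noncarcinogenic) or CR (carcinogenic).
#'
#' @inheritParams healthRisk
#' @param mode which THI to tabulate.
#' @return list with \code{perMetal} (group, cohort, metal, and min/max/
#'   mean/sd for cdi, hq, cr) and \code{thi} (group, cohort, min, max,
#'   mean).
#' @export
riskSummary <- function(x, metals = c("Cr", "Ni", "Mn"),
                        profiles = exposureProfiles(),
                        toxicity = defaultToxicity(),
                        mode = c("carcinogenic", "noncarcinogenic")) {
    mode <- match.arg(mode)
    hr <- healthRisk(x, metals, profiles, toxicity)$perSample
    stat <- function(v) c(min = min(v, na.rm = TRUE),
                          max = max(v, na.rm = TRUE),
                          mean = mean(v, na.rm = TRUE),
                          sd = stats::sd(v[!is.na(v)]))
    key <- unique(hr[, c("group", "cohort", "metal")])
    perMetal <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
        sub <- hr[hr$group == key$group[i] & hr$cohort == key$cohort[i] &
                  hr$metal == key$metal[i], ]
        out <- key[i, , drop = FALSE]
        for (q in c("cdi", "hq", "cr")) {
            v <- sub[[q]]
            s <- if (all(is.na(v))) c(min = NA_real_, max = NA_real_,
                                      mean = NA_real_, sd = NA_real_)
                 else stat(v)
            out[paste0(q, "_", names(s))] <- s
        }
        out
    }))
    rownames(perMetal) <- NULL
    qcol <- if (mode == "carcinogenic") "cr" else "hq"
    keep <- perMetal[!is.na(perMetal[[paste0(qcol, "_min")]]), ]
    thi <- stats::aggregate(
        keep[paste0(qcol, c("_min", "_max", "_mean"))],
        by = keep[c("group", "cohort")], FUN = sum)
    names(thi) <- c("group", "cohort", "min", "max", "mean")
    list(perMetal = perMetal, thi = thi)
}
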