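#' Aqueous species registry for the speciation engine
#'
#' Molar masses (g/mol) and charges of the species the minimal engine
#' tracks. Versioned data, overridable by the caller.
#'
#' @return data.frame with \code{species}, \code{molar_mass}, \code{charge}.
#' @export
speciesTable <- function() {
    tab <- data.frame(
        species    = c("Na", "K", "Ca", "Mg", "Mn",
                       "HCO3", "CO3", "Cl", "SO4", "NO3", "PO4",
                       "H", "OH"),
        molar_mass = c(22.99, 39.098, 40.08, 24.305, 54.938,
                       61.017, 60.009, 35.453, 96.06, 62.004, 94.971,
                       1.008, 17.007),
        charge     = c(1, 1, 2, 2, 2, -1, -2, -1, -2, -1, -3, 1, -1),
        stringsAsFactors = FALSE)
    attr(tab, "version") <- "1.0"
    tab
}

#' Ionic strength
#'
#' \code{I = 0.5 * sum(m_i * z_i^2)} in mol/kg.
#'
#' @param molality named vector of species molalities (mol/kg); names must
#'   be registered in \code{\link{speciesTable}} unless \code{charge} is
#'   supplied.
#' @param charge optional charges matching \code{molality}.
#' @return ionic strength (mol/kg).
#' @examples
#' ionicStrength(c(Na = 0.01, Cl = 0.01))          # 0.01
#' ionicStrength(c(Ca = 0.01, Cl = 0.02))          # 0.03
#' @export
ionicStrength <- function(molality, charge = NULL) {
    if (any(molality < 0, na.rm = TRUE)) stop("molalities must be >= 0")
    if (is.null(charge)) {
        tab <- speciesTable()
        i <- match(names(molality), tab$species)
        if (any(is.na(i)))
            stop("unknown species: ",
                 paste(names(molality)[is.na(i)], collapse = ", "))
        charge <- tab$charge[i]
    }
    0.5 * sum(molality * charge^2, na.rm = TRUE)
}

#' Davies activity coefficient
#'
#' \code{log10(gamma) = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - 0.3 I)} with
#' A = 0.5092 at 25 degrees C. Emits a warning beyond the model's usual
#' validity (I > 0.7 mol/kg).
#'
#' @param z species charge (0 for neutral species).
#' @param I ionic strength, mol/kg, >= 0.
#' @param A Debye-Huckel constant (0.5092 at 25 C).
#' @return activity coefficient gamma.
#' @examples
#' daviesGamma(1, 0.1)  # ~0.7816
#' @export
daviesGamma <- function(z, I, A = 0.5092) {
    if (any(I < 0)) stop("ionic strength must be >= 0")
    if (any(I > 0.7))
        warning("ionic strength > 0.7 mol/kg: outside Davies validity")
    sqI <- sqrt(I)
    10^(-A * z^2 * (sqI / (1 + sqI) - 0.3 * I))
}

#' Bundled mineral phases
#'
#' A small set of simple congruent phases with solubility products at
#' 25 degrees C. \code{stoich} maps species to dissolution-reaction
#' coefficients (products positive); brucite is stored in the
#' proton-dissolution convention Mg(OH)2 + 2 H+ = Mg2+ + 2 H2O, hence the
#' negative H coefficient and positive log K. Versioned and overridable.
#'
#' @return named list of minerals, each \code{list(logK, stoich)}.
#' @export
mineralTable <- function() {
    tab <- list(
        calcite       = list(logK = -8.48,  stoich = c(Ca = 1, CO3 = 1)),
        aragonite     = list(logK = -8.34,  stoich = c(Ca = 1, CO3 = 1)),
        dolomite      = list(logK = -17.09, stoich = c(Ca = 1, Mg = 1, CO3 = 2)),
        gypsum        = list(logK = -4.58,  stoich = c(Ca = 1, SO4 = 1)),
        anhydrite     = list(logK = -4.36,  stoich = c(Ca = 1, SO4 = 1)),
        halite        = list(logK = 1.570,  stoich = c(Na = 1, Cl = 1)),
        rhodochrosite = list(logK = -11.13, stoich = c(Mn = 1, CO3 = 1)),
        brucite       = list(logK = 16.84,  stoich = c(Mg = 1, H = -2)))
    attr(tab, "version") <- "1.0"
    tab
}

#' Solution state from measured concentrations
#'
#' Converts mg/L concentrations to molalities (dilute approximation
#' mol/L ~ mol/kg), computes ionic strength, Davies activity coefficients
#' and activities. H+ activity comes from pH; carbonate is derived from
#' bicarbonate and pH through the second carbonic-acid dissociation
#' constant K2 = 10^-10.33: \code{a(CO3) = K2 * a(HCO3) / a(H)}.
#'
#' @param conc named mg/L concentrations (subset of
#'   \code{\link{speciesTable}} species, e.g. Na, Ca, Mg, Mn, HCO3, Cl,
#'   SO4); temperature fixed at 25 C.
#' @param pH solution pH.
#' @param logK2 log10 of the HCO3-/CO3-- dissociation constant.
#' @return list of class \code{"solutionState"}: \code{molality},
#'   \code{gamma}, \code{activity} (all named), \code{I}, \code{pH},
#'   \code{temp_C}.
#' @export
solutionState <- function(conc, pH, logK2 = -10.33) {
    if (pH < 0 || pH > 14) stop("pH out of range")
    tab <- speciesTable()
    i <- match(names(conc), tab$species)
    if (any(is.na(i)))
        stop("unknown species: ", paste(names(conc)[is.na(i)], collapse = ", "))
    ## mg/L -> mol/L (~ mol/kg in dilute solution)
    mol <- stats::setNames(conc / tab$molar_mass[i] / 1000, names(conc))
    charge <- stats::setNames(tab$charge[i], names(conc))
    aH <- 10^(-pH)
    mH <- aH  # dilute: activity ~ molality for the proton budget
    I <- ionicStrength(c(mol, H = mH), c(charge, 1))
    gamma <- stats::setNames(daviesGamma(charge, I), names(mol))
    activity <- mol * gamma
    activity["H"] <- aH
    gamma["H"] <- 1
    if ("HCO3" %in% names(activity)) {
        aCO3 <- 10^logK2 * activity[["HCO3"]] / aH
        activity["CO3"] <- aCO3
        gamma["CO3"] <- daviesGamma(-2, I)
        mol["CO3"] <- aCO3 / gamma[["CO3"]]
    }
    structure(list(molality = mol, gamma = gamma, activity = activity,
                   I = I, pH = pH, temp_C = 25),
              class = "solutionState")
}

#' Mineral saturation index
#'
#' \code{SI = log10(IAP) - log10(K)} with the ion activity product taken
#' over the mineral's dissolution stoichiometry. SI > 0: supersaturated
#' (precipitation-prone); SI < 0: undersaturated (dissolution-prone).
#' The classification threshold defaults to 0 (the standard convention);
#' it is configurable.
#'
#' @param solution a \code{\link{solutionState}}, or a named vector of
#'   activities.
#' @param mineral a mineral name from \code{\link{mineralTable}}, or a
#'   \code{list(logK, stoich)}.
#' @param minerals the mineral registry to look names up in.
#' @param threshold classification threshold on SI.
#' @return list with \code{si}, \code{logIAP}, \code{logK}, \code{state}
#'   (\code{"supersaturated"}, \code{"undersaturated"} or
#'   \code{"equilibrium"}).
#' @export
saturationIndex <- function(solution, mineral, minerals = mineralTable(),
                            threshold = 0) {
    act <- if (inherits(solution, "solutionState")) solution$activity
           else solution
    if (is.character(mineral)) {
        if (!mineral %in% names(minerals)) stop("unknown mineral: ", mineral)
        mineral <- minerals[[mineral]]
    }
    st <- mineral$stoich
    missing <- setdiff(names(st), names(act))
    if (length(missing))
        stop("species missing from solution: ",
             paste(missing, collapse = ", "))
    logIAP <- sum(st * log10(act[names(st)]))
    si <- logIAP - mineral$logK
    state <- if (si > threshold) "supersaturated"
             else if (si < threshold) "undersaturated" else "equilibrium"
    list(si = si, logIAP = logIAP, logK = mineral$logK, state = state)
}

#' Saturation indices for all samples of a survey
#'
#' @param x a \linkS4class{WaterChemSet} with pH and the major ions.
#' @param minerals mineral registry (default \code{\link{mineralTable}}).
#' @return data.frame: \code{sample_id}, \code{mineral}, \code{si},
#'   \code{state}, \code{ionic_strength}.
#' @export
speciateSamples <- function(x, minerals = mineralTable()) {
    conc <- concMatrix(x)
    species <- intersect(rownames(conc), speciesTable()$species)
    res <- do.call(rbind, lapply(seq_len(ncol(conc)), function(j) {
        cv <- conc[species, j]
        cv <- cv[!is.na(cv)]
        sol <- solutionState(cv, pH = conc["pH", j])
        do.call(rbind, lapply(names(minerals), function(mn) {
            st <- minerals[[mn]]$stoich
            if (!all(names(st) %in% names(sol$activity))) return(NULL)
            s <- saturationIndex(sol, minerals[[mn]])
            data.frame(sample_id = colnames(conc)[j], mineral = mn,
                       si = s$si, state = s$state,
                       ionic_strength = sol$I)
        }))
    }))
    rownames(res) <- NULL
    res
}
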