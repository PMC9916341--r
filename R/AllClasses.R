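#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
NULL

.WATER_GROUPS <- c("mining", "non_mining", "mine_water")

## Canonical measured-parameter vocabulary (assay row names).
.PHYSCHEM_PARAMS <- c("pH", "EC", "TDS", "Turbidity", "ORP", "Temp")
.ION_PARAMS      <- c("Na", "K", "Ca", "Mg", "HCO3", "Cl", "SO4", "NO3", "PO4")
.METAL_PARAMS    <- c("Cr", "Ni", "Mn")
.ALL_PARAMS      <- c(.PHYSCHEM_PARAMS, .ION_PARAMS, .METAL_PARAMS)

## Parameters that may legitimately be negative (redox potential) or are
## two-sided (temperature); everything else must be >= 0 where measured.
.SIGNED_PARAMS <- c("ORP", "Temp")

#' WaterChemSet: per-well groundwater chemistry
#'
#' An S4 container for a groundwater survey, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"conc"} holds
#' measured values with parameters as rows and samples (wells) as columns:
#' physicochemical variables (pH, EC in uS/cm, TDS in mg/L, turbidity in NTU,
#' ORP in mV, temperature in degrees C), major ions and heavy metals in mg/L.
#' Sample metadata (group label, planar coordinates, well depth and surface
#' elevation) live in \code{colData}; per-parameter units in \code{rowData}.
#'
#' Validity requires: all concentrations (everything except ORP and
#' temperature) nonnegative where measured, pH within [0, 14], the group
#' label one of \code{"mining"}, \code{"non_mining"}, \code{"mine_water"},
#' and row names drawn from the registered parameter vocabulary.
#'
#' @seealso \code{\link{WaterChemSet}} (constructor),
#'   \code{\link{readWaterSamples}}, \code{\link{icbe}},
#'   \code{\link{groupSummary}}
#' @aliases WaterChemSet-class
#' @exportClass WaterChemSet
setClass("WaterChemSet", contains = "SummarizedExperiment")

setValidity("WaterChemSet", function(object) {
    msg <- character()
    if (!"conc" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'conc' is required")
    unknown <- setdiff(rownames(object), .ALL_PARAMS)
    if (length(unknown))
        msg <- c(msg, paste0("unknown parameters: ",
                             paste(unknown, collapse = ", ")))
    cd <- colData(object)
    if (!"group" %in% names(cd)) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else if (!all(as.character(cd$group) %in% .WATER_GROUPS)) {
        msg <- c(msg, paste0("group labels must be one of: ",
                             paste(.WATER_GROUPS, collapse = ", ")))
    }
    if ("conc" %in% names(SummarizedExperiment::assays(object))) {
        conc <- SummarizedExperiment::assay(object, "conc")
        nonneg <- setdiff(rownames(conc), .SIGNED_PARAMS)
        vals <- conc[nonneg, , drop = FALSE]
        if (any(vals < 0, na.rm = TRUE))
            msg <- c(msg, "negative concentrations found (only ORP/Temp may be signed)")
        if ("pH" %in% rownames(conc)) {
            ph <- conc["pH", ]
            if (any(ph < 0 | ph > 14, na.rm = TRUE))
                msg <- c(msg, "pH outside [0, 14]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' PMFFit: a fitted positive matrix factorization model
#'
#' Result of \code{\link{fitPMF}}: the data matrix \code{X} (samples x
#' parameters), uncertainty matrix \code{U}, nonnegative contribution matrix
#' \code{G} (samples x factors), nonnegative profile matrix \code{F}
#' (factors x parameters), the uncertainty-weighted objective values
#' \code{qTrue} and \code{qRobust}, and solver bookkeeping.
#'
#' @slot X numeric matrix, samples x parameters.
#' @slot U numeric matrix of uncertainties, same shape as \code{X}.
#' @slot G numeric matrix of factor contributions, samples x factors.
#' @slot F numeric matrix of factor profiles, factors x parameters.
#' @slot qTrue numeric(1), sum of squared uncertainty-scaled residuals.
#' @slot qRobust numeric(1), objective with scaled residuals capped at 4.
#' @slot converged logical(1).
#' @slot nIter integer(1), iterations used by the winning start.
#' @slot nStarts integer(1), random initializations tried.
#' @slot seed integer(1), seed used for the random initializations.
#' @slot qPath numeric, per-iteration objective of the winning start
#'   (nonincreasing).
#' @aliases PMFFit-class
#' @exportClass PMFFit
setClass("PMFFit",
    representation(X = "matrix", U = "matrix", G = "matrix", F = "matrix",
                   qTrue = "numeric", qRobust = "numeric",
                   converged = "logical", nIter = "integer",
                   nStarts = "integer", seed = "integer",
                   qPath = "numeric"))

setValidity("PMFFit", function(object) {
    msg <- character()
    if (any(object@G < 0) || any(object@F < 0))
        msg <- c(msg, "G and F must be nonnegative")
    if (!identical(dim(object@X), dim(object@U)))
        msg <- c(msg, "X and U must have identical dimensions")
    if (nrow(object@G) != nrow(object@X) || ncol(object@F) != ncol(object@X))
        msg <- c(msg, "G/F dimensions inconsistent with X")
    if (ncol(object@G) != nrow(object@F))
        msg <- c(msg, "number of factors inconsistent between G and F")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PMFFit", function(object) {
    cat("PMFFit:", nrow(object@X), "samples x", ncol(object@X),
        "parameters,", ncol(object@G), "factors\n")
    cat(sprintf("  Q(true) = %.4g, Q(robust) = %.4g, ratio = %.3f\n",
                object@qTrue, object@qRobust,
                object@qTrue / max(object@qRobust, .Machine$double.eps)))
    cat(sprintf("  best of %d starts (seed %d), %d iterations, %s\n",
                object@nStarts, object@seed, object@nIter,
                if (object@converged) "converged" else "NOT converged"))
})
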