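#' Construct a WaterChemSet
#'
#' @param conc numeric matrix of measured values, parameters as rows (names
#'   drawn from \code{\link{parameterVocabulary}()}) and samples as columns.
#' @param sampleData data.frame (or DataFrame) of per-sample metadata; must
#'   contain \code{group} (one of \code{"mining"}, \code{"non_mining"},
#'   \code{"mine_water"}); typically also \code{x}, \code{y},
#'   \code{depth_m}, \code{elevation_m}.
#' @return A \linkS4class{WaterChemSet}.
#' @examples
#' conc <- matrix(c(7.5, 650, 0.9), nrow = 3,
#'                dimnames = list(c("pH", "EC", "Cr"), "W1"))
#' wcs <- WaterChemSet(conc, data.frame(group = "mining", row.names = "W1"))
#' @export
WaterChemSet <- function(conc, sampleData) {
    conc <- as.matrix(conc)
    storage.mode(conc) <- "double"
    sampleData <- S4Vectors::DataFrame(sampleData)
    sampleData$group <- factor(as.character(sampleData$group),
                               levels = .WATER_GROUPS)
    rd <- S4Vectors::DataFrame(unit = parameterUnits(rownames(conc)),
                               row.names = rownames(conc))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(conc = conc),
        colData = sampleData, rowData = rd)
    methods::new("WaterChemSet", se)
}

#' Measured-parameter vocabulary
#'
#' @return Character vector of the registered parameter names, in canonical
#'   order: physicochemical variables, major ions, heavy metals.
#' @export
parameterVocabulary <- function() .ALL_PARAMS

.PARAM_UNITS <- c(pH = "unitless", EC = "uS/cm", TDS = "mg/L",
                  Turbidity = "NTU", ORP = "mV", Temp = "degC",
                  Na = "mg/L", K = "mg/L", Ca = "mg/L", Mg = "mg/L",
                  HCO3 = "mg/L", Cl = "mg/L", SO4 = "mg/L", NO3 = "mg/L",
                  PO4 = "mg/L", Cr = "mg/L", Ni = "mg/L", Mn = "mg/L")

parameterUnits <- function(params) unname(.PARAM_UNITS[params])

#' @describeIn WaterChemSet concentration (assay) matrix, parameters x samples.
#' @param x a WaterChemSet.
#' @export
concMatrix <- function(x) SummarizedExperiment::assay(x, "conc")

#' @describeIn WaterChemSet per-sample group factor.
#' @export
sampleGroup <- function(x) colData(x)$group

#' @describeIn WaterChemSet two-column matrix of planar sample coordinates.
#' @export
sampleCoords <- function(x) {
    cd <- colData(x)
    cbind(x = cd$x, y = cd$y)
}

setMethod("show", "WaterChemSet", function(object) {
    cat("WaterChemSet:", ncol(object), "samples x", nrow(object),
        "parameters\n")
    tab <- table(sampleGroup(object))
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
    cat("  parameters:", paste(rownames(object), collapse = ", "), "\n")
})

## Fixed CSV schema: one row per sample.
.CSV_PARAM_MAP <- c(ph = "pH", ec_uScm = "EC", tds_mgL = "TDS",
                    turbidity_NTU = "Turbidity", orp_mV = "ORP",
                    temp_C = "Temp",
                    na_mgL = "Na", k_mgL = "K", ca_mgL = "Ca", mg_mgL = "Mg",
                    hco3_mgL = "HCO3", cl_mgL = "Cl", so4_mgL = "SO4",
                    no3_mgL = "NO3", po4_mgL = "PO4",
                    cr_mgL = "Cr", ni_mgL = "Ni", mn_mgL = "Mn")
.CSV_META_COLS <- c("sample_id", "group", "x", "y", "depth_m", "elevation_m")

#' Read a per-sample groundwater chemistry CSV
#'
#' Reads the fixed one-row-per-sample schema (columns \code{sample_id},
#' \code{group}, \code{x}, \code{y}, \code{depth_m}, \code{elevation_m},
#' \code{ph}, \code{ec_uScm}, \code{tds_mgL}, \code{turbidity_NTU},
#' \code{orp_mV}, \code{temp_C}, then the ions and metals as
#' \code{na_mgL} ... \code{mn_mgL}), validates it and returns a
#' \linkS4class{WaterChemSet}. Missing cells are kept as \code{NA}
#' ("not measured"); they are never imputed as zero. Per-row QC issues
#' (negative concentrations, pH out of range, unknown group) raise errors
#' via the class validity check.
#'
#' @param file path to a CSV file.
#' @return A \linkS4class{WaterChemSet}.
#' @export
readWaterSamples <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(c("sample_id", "group"), names(df))
    if (length(missing))
        stop("required columns absent: ", paste(missing, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id values")
    have <- intersect(names(.CSV_PARAM_MAP), names(df))
    if (!length(have))
        stop("no measured-parameter columns found")
    conc <- t(as.matrix(df[, have, drop = FALSE]))
    rownames(conc) <- unname(.CSV_PARAM_MAP[have])
    colnames(conc) <- df$sample_id
    meta <- df[, intersect(.CSV_META_COLS, names(df)), drop = FALSE]
    meta$sample_id <- NULL
    rownames(meta) <- df$sample_id
    WaterChemSet(conc, meta)
}

#' Write a WaterChemSet to the fixed CSV schema
#'
#' Inverse of \code{\link{readWaterSamples}}.
#'
#' @param x a \linkS4class{WaterChemSet}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeWaterSamples <- function(x, file) {
    conc <- concMatrix(x)
    cd <- as.data.frame(colData(x))
    out <- data.frame(sample_id = colnames(x), stringsAsFactors = FALSE)
    for (col in setdiff(.CSV_META_COLS, "sample_id"))
        if (col %in% names(cd)) out[[col]] <- cd[[col]]
    for (csv in names(.CSV_PARAM_MAP)) {
        p <- .CSV_PARAM_MAP[[csv]]
        if (p %in% rownames(conc)) out[[csv]] <- conc[p, ]
    }
    utils::write.csv(out, file, row.names = FALSE)
    invisible(file)
}

#' Per-group summary statistics
#'
#' Minimum, maximum, mean and sample (n-1) standard deviation of every
#' measured parameter, per group. With a single observation the standard
#' deviation is undefined and reported as 0 with \code{degenerate = TRUE}.
#'
#' @param x a \linkS4class{WaterChemSet}.
#' @param params parameters to summarize (default: all rows).
#' @return data.frame with columns \code{group}, \code{parameter}, \code{n},
#'   \code{min}, \code{max}, \code{mean}, \code{sd}, \code{degenerate}.
#' @export
groupSummary <- function(x, params = rownames(x)) {
    conc <- concMatrix(x)[params, , drop = FALSE]
    grp <- sampleGroup(x)
    groups <- levels(droplevels(grp))
    if (!length(groups)) stop("no samples in any group")
    res <- do.call(rbind, lapply(groups, function(g) {
        m <- conc[, grp == g, drop = FALSE]
        if (!ncol(m)) stop("empty group: ", g)
        do.call(rbind, lapply(rownames(m), function(p) {
            v <- m[p, ]
            v <- v[!is.na(v)]
            n <- length(v)
            data.frame(group = g, parameter = p, n = n,
                       min = if (n) min(v) else NA_real_,
                       max = if (n) max(v) else NA_real_,
                       mean = if (n) mean(v) else NA_real_,
                       sd = if (n > 1) stats::sd(v) else 0,
                       degenerate = n < 2)
        }))
    }))
    rownames(res) <- NULL
    res
}
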