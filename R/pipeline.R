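#' Default PMF parameter set for a groundwater survey
#'
#' The 16 nonnegative measured variables customarily entered into the
#' receptor models (pH, EC, TDS, turbidity, the major ions and the
#' metals); ORP and temperature are excluded.
#' @return character vector of parameter names.
#' @export
receptorParams <- function() {
    c("pH", "EC", "TDS", "Turbidity",
      "Na", "K", "Mg", "Ca", "PO4", "NO3", "HCO3", "Cl", "SO4",
      "Cr", "Ni", "Mn")
}

#' Samples-by-parameters matrix for multivariate stages
#'
#' @param x a \linkS4class{WaterChemSet}.
#' @param params assay rows to extract.
#' @param wellGeometry also bind depth_m / elevation_m from colData.
#' @return numeric matrix, samples x variables.
#' @export
chemMatrix <- function(x, params = receptorParams(), wellGeometry = FALSE) {
    params <- intersect(params, rownames(x))
    M <- t(concMatrix(x)[params, , drop = FALSE])
    if (wellGeometry) {
        cd <- colData(x)
        for (col in c("depth_m", "elevation_m"))
            if (col %in% names(cd)) M <- cbind(M, stats::setNames(
                data.frame(cd[[col]]), col))
        M <- as.matrix(M)
    }
    M
}

#' Default detection limits for the uncertainty model
#'
#' Laboratory detection limits where reported (Cr 0.1, Ni 0.5 mg/L);
#' other parameters default to 2% of their observed median.
#'
#' @param X samples x parameters matrix.
#' @return named MDL vector.
#' @export
defaultMDL <- function(X) {
    mdl <- apply(X, 2, function(v) 0.02 * stats::median(v, na.rm = TRUE))
    known <- c(Cr = 0.1, Ni = 0.5)
    hit <- intersect(names(known), names(mdl))
    mdl[hit] <- known[hit]
    mdl
}

.PIPELINE_STAGES <- c("qc", "indices", "facies", "hhra", "clustering",
                      "sources", "speciation", "spatial")

#' Run the full assessment pipeline
#'
#' Executes QC (charge balance), pollution indices, facies, health risk,
#' clustering, source apportionment (PMF + APCS-MLR), saturation indices
#' and kriging, writing one CSV/JSON per stage plus a run manifest.
#' Outputs are a pure function of (input, configuration, seed): the
#' manifest carries no timestamps, so a rerun with the same inputs is
#' file-identical.
#'
#' @param input a \linkS4class{WaterChemSet} or a path to the fixed-schema
#'   CSV (see \code{\link{readWaterSamples}}).
#' @param outDir output directory (created if needed).
#' @param stages subset of
#'   \code{c("qc","indices","facies","hhra","clustering","sources",
#'   "speciation","spatial")}.
#' @param seed integer seed for the stochastic stages.
#' @param standards guideline limits.
#' @param nFactors factors for the receptor models.
#' @param kClusters clusters for HACA.
#' @param krigeParam parameter to interpolate.
#' @param resolution kriging grid cells per axis.
#' @return invisibly, a named list of output file paths.
#' @export
runPipeline <- function(input, outDir, stages = .PIPELINE_STAGES, seed = 1,
                        standards = whoStandards(), nFactors = 3,
                        kClusters = 3, krigeParam = "Cr", resolution = 25) {
    wcs <- if (methods::is(input, "WaterChemSet")) input
           else readWaterSamples(input)
    stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    emit <- function(name, df) {
        p <- file.path(outDir, paste0(name, ".csv"))
        utils::write.csv(df, p, row.names = FALSE)
        message("[", name, "] wrote ", nrow(df), " rows")
        paths[[name]] <<- p
    }
    log <- list(seed = seed, n_samples = ncol(wcs),
                n_parameters = nrow(wcs), stages = stages,
                package_version = as.character(utils::packageVersion("aquarisk")))
    if ("qc" %in% stages) {
        emit("qc_icbe", icbe(wcs))
        emit("group_summary", groupSummary(wcs))
    }
    if ("indices" %in% stages) {
        emit("indices_npi", nemerowIndex(wcs, standards))
        emit("indices_exceedance", exceedanceTable(wcs, standards))
    }
    if ("facies" %in% stages) {
        emit("facies", cbind(gibbsCoords(wcs),
                             chadhaClassify(wcs)[, -1]))
        emit("facies_tally", faciesTally(wcs))
    }
    if ("hhra" %in% stages) {
        rs <- riskSummary(wcs)
        emit("risk_per_metal", rs$perMetal)
        emit("risk_thi_carcinogenic", rs$thi)
        emit("risk_per_sample", healthRisk(wcs)$perSample)
    }
    if ("clustering" %in% stages) {
        cl <- haca(wcs, params = receptorParams(), k = kClusters)
        emit("clusters", data.frame(sample_id = colnames(wcs),
                                    cluster = cl$labels))
        if (kClusters == 3)
            emit("cluster_severity", severityRanking(cl,
                                                     standards = standards))
        writeLines(dendrogramExport(cl$tree)$newick,
                   file.path(outDir, "dendrogram.nwk"))
        paths[["dendrogram"]] <- file.path(outDir, "dendrogram.nwk")
    }
    if ("sources" %in% stages) {
        X <- chemMatrix(wcs)
        U <- buildUncertainty(X, defaultMDL(X))
        fit <- fitPMF(X, U, p = nFactors, nStarts = 20, seed = seed)
        emit("pmf_profiles", data.frame(factor = seq_len(nFactors), fit@F))
        emit("pmf_contributions", data.frame(sample_id = rownames(X),
                                             fit@G))
        diag <- list(qTrue = fit@qTrue, qRobust = fit@qRobust,
                     ratio = fit@qTrue / fit@qRobust,
                     converged = fit@converged,
                     sn = as.list(signalToNoise(X, U)),
                     r2 = as.list(reconstructionR2(fit)))
        jp <- file.path(outDir, "pmf_diagnostics.json")
        jsonlite::write_json(diag, jp, auto_unbox = TRUE, digits = NA)
        paths[["pmf_diagnostics"]] <- jp
        ap <- apcsMlr(X, nFactors = nFactors)
        emit("apcs_contributions",
             data.frame(factor = names(ap$contributions),
                        percent = as.numeric(ap$contributions),
                        r2 = ap$r2))
    }
    if ("speciation" %in% stages) emit("saturation_indices",
                                       speciateSamples(wcs))
    if ("spatial" %in% stages) {
        set.seed(seed)
        emit("krige_raster", krigeGrid(wcs, krigeParam,
                                       resolution = resolution))
    }
    mp <- file.path(outDir, "manifest.json")
    jsonlite::write_json(log, mp, auto_unbox = TRUE, digits = NA)
    paths[["manifest"]] <- mp
    invisible(paths)
}
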