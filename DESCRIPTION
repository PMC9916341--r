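Package: aquarisk
Title: Groundwater Quality Indices, Health Risk and Source Apportionment
    for Mining-Impacted Aquifers
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the hydrogeochemical assessment of groundwater around
    metal (chromite) mining operations. Provides a SummarizedExperiment-based
    container for per-well chemistry, ion charge-balance quality control,
    Nemerow and single-factor pollution indices against WHO guideline limits,
    Gibbs and Chadha hydrochemical facies classification, a deterministic
    oral-ingestion human health risk chain (chronic daily intake, hazard
    quotient, hazard and total hazard indices, incremental lifetime cancer
    risk), uncertainty-weighted positive matrix factorization and APCS-MLR
    receptor modelling for source apportionment, Ward hierarchical clustering
    with pollution-severity summaries, a minimal aqueous speciation engine
    (Davies activity model, carbonate system, mineral saturation indices),
    inverse-distance and ordinary-kriging spatial interpolation with
    five-class vulnerability classification, and a synthetic-data generator
    reproducing the three-group study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
biocViews: Software, QualityControl, Clustering, PrincipalComponent
RoxygenNote: 7.3.3
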