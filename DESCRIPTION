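Package: mossPAH
Title: Herbarium Moss Biomonitoring of Polycyclic Aromatic Hydrocarbon
    Deposition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing historical atmospheric polycyclic
    aromatic hydrocarbon (PAH) deposition from herbarium moss specimens
    analysed by targeted GC-MS. Covers internal-standard calibration and
    quantification of peak areas to ng per g dry weight, handling of values
    censored at compound-specific limits of quantification, prevalence
    filtering and log transformation, decade and fuel-era grouping, period
    summary tables with low/high molecular weight accounting, column
    Z-score matrices, per-compound ANOVA with Tukey HSD contrasts and
    Benjamini-Hochberg false-discovery-rate correction, Bray-Curtis
    chemical dissimilarity analysis, and diagnostic-ratio source
    apportionment (petrogenic versus pyrogenic attribution). A seeded
    synthetic-data generator emulates a multi-decade herbarium study so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
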