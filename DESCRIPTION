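Package: lipidshift
Title: Stratified Differential Abundance and Biomarker Screening for Targeted Plasma Lipidomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted plasma lipidomic panels in case-control
    designs. Parses LIPID MAPS shorthand names for acylcarnitines,
    phosphatidylcholines, lysophosphatidylcholines, ether-linked
    phosphatidylcholines and sphingomyelins; derives structural (Total FA,
    total carbon, double bonds, hydroxylation, ether bond, saturation) and
    rule-based biophysical annotations; performs Wilcoxon-Mann-Whitney
    differential abundance with Benjamini-Hochberg correction at the species
    level and across structural strata; runs shadow-attribute (Boruta-style)
    feature selection under a two-condition resampling stability protocol with
    shadow-ratio diagnostics; screens biomarker candidates by ROC AUC with
    DeLong confidence intervals and Youden-optimal thresholds; and maps
    significant lipids to candidate metabolic genes as a bipartite network.
    Includes a synthetic cohort generator emulating a Biocrates p180-style
    panel so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    optparse
Config/testthat/edition: 3
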