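Package: qhtcp
Title: Quantitative Phenomic Screening of Arrayed Yeast Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chemogenomic fitness screens of arrayed
    microbial cultures imaged over time (quantitative high-throughput cell
    array phenotyping). Fits per-spot logistic growth curves to extract cell
    proliferation parameters (carrying capacity K, maximum specific growth
    rate r, and time L to half carrying capacity), standardizes them to
    plate-level z-scores against reference-strain arrays, derives adjusted
    z-scores as gene-drug interaction statistics, classifies enhancing and
    suppressing deletions, clusters interaction profiles with a BIC-optimal
    cut of the hierarchical tree, and tests clusters for Gene Ontology term
    over-representation with Benjamini-Hochberg correction. Also provides
    liquid-assay dose-response tools: four-parameter logistic IC50 fitting,
    growth-curve lag and maximum-rate metrics, and zero interaction potency
    (ZIP) delta-score synergy surfaces for drug combination matrices.
    Includes a fully seeded synthetic-screen generator with known ground
    truth for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
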