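Package: dietswitch
Title: Diet-Switch Time-Course Expression and Mortality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for acute diet-switch experiments in
    Drosophila: simulation of three-cohort (control, restricted, switched)
    log2 expression time courses and Gompertz survival cohorts with known
    ground truth; life-table construction, instantaneous hazard estimation,
    log-rank comparison and detection of mortality separation and
    post-switch convergence; time-paired differential expression with a
    pooled Benjamini-Hochberg false discovery rate; classification of genes
    into temporal-response categories (switching, refractory, responsive,
    deviating, null and indeterminate classes); direction-aware
    hypergeometric gene-set over-representation over GMT annotations; and
    cross-study direction-concordance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
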