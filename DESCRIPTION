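Package: evftir
Title: Mid-Infrared Spectral Biomarkers for Extracellular-Vesicle Liquid Biopsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for ATR-FTIR spectra of serum extracellular-vesicle
    (EV) preparations used as a cancer liquid biopsy. Implements the full
    chain from spectral ingestion (CSV, minimal JCAMP-DX) through linear
    baseline subtraction and area/vector/max normalization, integrated
    mid-infrared band areas and the lipid-to-protein (LPR) and
    lipid-to-nucleic-acid (LNR) spectral ratios, PCA-LDA band-shape scoring
    with leave-one-out cross-validation, and biomarker evaluation by Wilcoxon
    rank-sum tests, empirical ROC curves with DeLong confidence intervals,
    Youden and closest-top-left operating points, and stepwise logistic
    marker combination. A synthetic spectrum and feature-cohort generator
    reproduces the statistical structure of a two-group
    hepatocellular-carcinoma case/control study so that every stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    optparse
Config/testthat/edition: 3
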