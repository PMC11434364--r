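Package: urinmr
Title: Urinary 1H-NMR Metabolomics: Spectral Processing, TSP Quantification
    and Visceral-Obesity Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for urinary one-dimensional proton NMR
    metabolomics. Simulates cohorts of free induction decays (FIDs) carrying a
    urine metabolite panel plus a TSP reference; processes them by exponential
    apodization, Fourier transformation, automated phasing, asymmetric
    least-squares baseline correction and chemical-shift calibration; profiles
    spectra by fixed-width binning with residual-water exclusion and principal
    component analysis; quantifies metabolites by per-signal spectral alignment
    and internal-standard referencing to absolute concentrations (mg/mL); and
    compares obesity groupings with nonparametric statistics, including ROC
    cutoff analysis with predictive values for visceral-fat biomarkers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
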