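Package: imodulator
Title: Robust ICA Decomposition of Expression Compendia into iModulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes quality-controlled bacterial expression compendia
    into independently modulated gene sets (iModulons) using robust
    independent component analysis. Provides the full pipeline: RNA-Seq
    quality control and normalization (gene filters, TPM, log transform,
    replicate correlation filter, reference centering), PCA-based
    dimensionality estimation, multi-restart FastICA with density-based
    consensus clustering of components, iterative D'Agostino K-squared
    membership thresholding, regulon enrichment with precision/recall and
    boolean regulator combinations, condition-level activity summaries with
    broken-line regulator concordance fits, a planted-module synthetic
    compendium generator for validation, and dataset summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ica,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
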