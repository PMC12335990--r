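Package: ThermoBench
Title: Statistical Workbench for Thermal Proteome Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data processing, curve fitting, and inference for thermal proteome
    profiling (TPP/CETSA) experiments with TMT labeling. Implements both
    protein-level processing protocols (reference-ratio normalization with a
    NormSet-derived sigmoid factor, and log2/filter/impute/median-polish
    summarization with reference-channel alignment), four competing per-protein
    statistical models (natural-spline fits with plain and moderated F-tests,
    sigmoid NPARC fits with empirical-Bayes rescaled degrees of freedom, a
    monotone shape-constrained additive model, and a mixed-effects cell-means
    model with temperature-subset contrasts and Satterthwaite degrees of
    freedom), a ground-truth simulator for thermal and OnePot designs with
    separate biological and technological variance components, and evaluation
    summaries for calibration, sensitivity, and design comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    minpack.lm,
    survival,
    limma,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'study_io.R'
    'inference.R'
    'mixed.R'
    'processing.R'
    'msstats_processing.R'
    'scam.R'
    'sigmoid.R'
    'simulator.R'
    'spline.R'
    'workbench.R'
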