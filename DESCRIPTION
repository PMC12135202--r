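Package: snadosage
Title: Steady-State Modeling and Inference of Negative Autoregulation from
    Gene Dosage Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of transcriptional negative autoregulation
    assayed by gene dosage (1-copy versus 2-copy expression ratios), built
    around the early Drosophila embryo gene snail. Provides steady-state
    solvers for Hill-function and step-function (Heaviside limit)
    self-repression models, closed-form inversion of dosage ratios into
    repression thresholds and net production rates, genotype categorization,
    a shifted-mean bootstrap test for embryonic viability with Bonferroni
    correction, fluorescence-quantification utilities (expression-domain
    detection, fold changes, one-way ANOVA with Tukey HSD), Mendelian
    balancer-cross expectations, and a synthetic-data generator that emulates
    per-embryo intensity tables, viability outcomes and striped embryo
    images from known ground-truth parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
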