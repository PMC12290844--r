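Package: lsmbias
Title: Dual Frequentist and Bayesian Lesion-Symptom Mapping with
    Subsampling Bias Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxelwise and regionwise lesion-symptom mapping for stroke
    cohorts, run side by side with frequentist mass-univariate linear
    models (false-discovery-rate and maximum-statistic permutation
    correction) and Bayes-factor evidence (BIC approximation or
    Jeffreys-Zellner-Siow default prior).  Includes tools for
    classifying behavioural deficits against clinical cut-offs,
    building sub-samples that isolate or exclude patients with shared
    deficits, resampling controls for small deficit groups, and
    diagnostics for the sampling-induced biases (dilution, cross-task
    positive bias, reverse "protective" associations) that arise when
    patients with shared and isolated deficits are analysed together.
    A synthetic lesion-cohort simulator with known ground-truth effect
    areas makes every stage of the pipeline testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
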