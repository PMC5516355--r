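Package: ladmass
Title: Logical Analysis of Data for Binned Mass-Spectral Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the logical analysis of data (LAD) methodology for
    two-class classification of binned mass-spectral intensity profiles, as
    used to separate rapid from slow progressors of chronic kidney disease
    from SELDI-TOF serum spectra. Provides cutpoint discretization, minimal
    support-set selection by greedy set cover (with an exhaustive oracle),
    bounded-degree conjunctive pattern enumeration scored by prevalence and
    homogeneity, greedy pattern-model selection, a discriminant-based risk
    score with quantile risk stratification and Mann-Whitney ROC/AUC, and a
    repeated stratified k-fold cross-validation harness. A synthetic SELDI-
    like cohort generator with planted discriminative masses, an insulin-like
    internal standard and calibrated between-replicate correlation provides a
    ground-truth test surface, together with 2-Da spectrum binning and
    internal-standard normalization preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
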