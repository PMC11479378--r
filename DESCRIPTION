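Package: hmmsm
Title: Hidden Markov Model Similarity for Wearable Gait Assessment
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies changes in gait patterns from lower-body inertial
    sensor recordings using a hidden Markov model similarity measure
    (HMM-SM). Gait cycles are grouped by stance-time symmetry ratio (STSR),
    ensembles of left-to-right Gaussian-emission HMMs are trained on each
    group by expectation-maximization, and pairwise model similarity is
    scored from the normalized Gini sparsity of a symmetric-KL state
    correspondence matrix. Includes a synthetic multichannel gait signal
    generator with controllable stance-time symmetry, a three-symmetry-level
    validity analysis (repeated-measures ANOVA and Bonferroni-corrected
    paired t-tests) and a two-symmetry-level split-half reliability analysis
    (ICC(3,1), SEM, MDC95).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
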