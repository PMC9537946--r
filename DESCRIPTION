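Package: elsconn
Title: Early-Life Stress and Resting-State Network Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking early-life stress (ELS) to
    resting-state functional network connectivity. Builds prospective
    cumulative-risk composites with expectation-maximization imputation and
    retrospective adverse-childhood-experience domain totals, turns ROI time
    series into 12x12 Pearson connectivity matrices and 66-edge profiles,
    and tests brain-behaviour association three ways: inter-subject
    representational similarity analysis (partial correlation of
    dissimilarity matrices with permutation inference), multivariate
    distance matrix regression (Gower centering, per-term trace statistics,
    pseudo R-squared, Freedman-Lane permutations), and univariate/edge-level
    statistics (Spearman and partial correlations, covariate-adjusted edge
    regressions with Benjamini-Hochberg correction, Steiger's test for
    dependent correlations, extreme-group edge contrasts). A seeded
    synthetic-cohort generator with plantable mean-level and pattern-level
    connectivity effects provides a parameter-recovery and null-calibration
    test surface, since studies of this design rarely share raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
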