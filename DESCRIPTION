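Package: scnvuln
Title: Vulnerable Brain Regions from Individualized Structural Covariance Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects brain regions whose structure is vulnerable to risk
    factors such as ApoE genotype, sex, age, innate immunity and diet, from
    individualized structural covariance networks. Per-subject networks are
    built as pairwise absolute differences of normalized regional volume and
    fractional anisotropy; subjects are jointly embedded per modality with the
    omnibus spectral embedding of a random dot product graph model, with the
    embedding dimension chosen by profile log-likelihood elbow detection;
    per-region latent features are concatenated across modalities and tested
    region-by-region against combinations of risk factors with the unbiased
    distance correlation, a fast chi-squared null approximation, and
    Holm-Bonferroni familywise error control. Includes a synthetic cohort
    generator with planted region-level effects for calibration and power
    studies, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
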