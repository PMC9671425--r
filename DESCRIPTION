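Package: wingmorph
Title: Landmark-Based Geometric Morphometrics of Insect Fore Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of insect fore
    wings, built around the workflow used to discriminate Darwin-wasp
    (Ichneumonidae) subfamilies by wing venation and to place compression
    fossils into the extant classification. Reads and writes TPS landmark
    files, performs generalized Procrustes analysis with optional sliding
    semilandmarks, permutation-based Procrustes ANOVA, allometric regression
    of shape on centroid size (raw and pooled within-group), per-group
    Procrustes variance and pairwise Procrustes distance summaries, canonical
    variate analysis with leave-one-out cross-validation and Cohen's Kappa,
    posterior-probability classification of new specimens, between-group PCA
    with permutation-tested distances to group averages, and an end-to-end
    fossil-placement pipeline with decision thresholds. Includes a synthetic
    wing-landmark generator with known ground truth for validation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
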