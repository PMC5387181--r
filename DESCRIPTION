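Package: neoconn
Title: Weighted Structural Connectome Analysis of the Developing Neonatal Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing weighted structural brain networks in neonates:
    construction of multi-weight connectomes from streamline counts and edge-wise
    microstructure (fraction of streamlines, FA, NDI, 1-ODI), cost-corrected and
    normalised graph topology over a density sweep, degree-preserving null models
    and small-worldness, betweenness-based core/local edge decomposition, and
    edge-wise association statistics in the minimum grid of connectivity with
    mixed-effects covariate control, partial Spearman correlation and FDR
    correction. Includes a seeded synthetic cohort generator that emulates the
    age, prematurity and repeated-scan structure of a neonatal MRI study so the
    whole pipeline is testable without imaging data.
License: MIT
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
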