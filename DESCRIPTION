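Package: lifespanephys
Title: Morphoelectric Feature Extraction and Lifespan Cohort Statistics for
    Cortical Pyramidal Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extraction of intrinsic electrophysiological features from
    current-clamp step recordings of cortical layer 2/3 pyramidal cells
    (subthreshold passive properties, action-potential waveform and
    afterpotential metrics, rheobase and firing-pattern indices), dendritic
    arbor morphometry and spine-density analysis on SWC reconstructions, and
    nonparametric age-group comparison across the human lifespan
    (Kruskal-Wallis with Dunn post-hoc, Monte-Carlo Lilliefors normality
    testing). Includes a seeded adaptive exponential integrate-and-fire
    membrane simulator with an h-current and a random morphology generator so
    the whole pipeline can be exercised on synthetic cohorts with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    generics,
    readr,
    ggplot2,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    pracma,
    cluster,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
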