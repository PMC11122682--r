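Package: morphdyn
Title: Negative Frequency-Dependent Selection Dynamics from Replicated
    Morph-Frequency Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicated time series of discrete
    colour-pattern morph frequencies evolving under negative
    frequency-dependent selection (NFDS). Estimates the NFDS strength
    parameter D and the equilibrium morph frequency from yearly count
    data with a hierarchical Bayesian latent-frequency model, classifies
    the expected dynamics (convergence, dampened, stable or diverging
    oscillations), tests for dampening of fluctuations over time,
    simulates NFDS-plus-drift null distributions of fluctuation
    magnitude with effective-population-size sensitivity analysis, fits
    linear and sigmoidal fitness functions to frequency-manipulation
    transplant experiments, and tests for heterozygote excess at
    structural-variant loci via PCA and k-means genotype clustering.
    Includes a synthetic-data generator that emulates the structure of
    multi-decade field surveys of morph counts, so the whole pipeline is
    testable end to end without field data.
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
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    coda,
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
VignetteBuilder: knitr
Config/testthat/edition: 3
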