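Package: p38nfkb
Title: Simulation and Analysis of Combinatorial p38 and NF-kB Signaling
    Dynamics in Single Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the stress kinase p38 and the
    transcription factor NF-kB jointly encode innate-immune stimulus
    identity and dose in single macrophages. Provides an ODE simulator of
    the branched IKK/Tpl2-MKK3/6 and TAK1-MKK4 pathways feeding p38,
    coupled to a reduced IkB-NF-kB negative-feedback module, with
    lognormal cell-to-cell parameter heterogeneity and module-wise
    "denoising"; trajectory preprocessing, responder calling and a
    dynamic-feature catalog; a discrete-continuous k-nearest-neighbour
    mutual-information estimator with jackknife subsample extrapolation;
    bagged decision-tree stimulus and dose classifiers with
    shuffled-pairing controls; four-parameter Hill dose-response fits;
    paired Spearman correlation structure and coefficients of variation;
    and an AND-gate mRNA synthesis/degradation model scored by Fano
    factor and bimodality coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    randomForest,
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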