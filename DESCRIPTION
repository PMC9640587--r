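Package: cppmap
Title: Place-Cell Remapping and Population Decoding Analysis for
    Conditioned Place Preference Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal one-photon calcium imaging
    of hippocampal CA1 during conditioned place preference (CPP) in a
    two-compartment arena. Provides a synthetic experiment generator
    (foraging trajectories, place-tuned deconvolved activity with planted
    across-session effects), occupancy-matched place-cell identification
    via spatial information and a place cell agreement index, functional
    cell typing (disappeared, appeared and retained place cells per
    compartment), multinomial naive Bayes position decoding with a two-step
    continuity constraint and computational knock-out, consensus k-means
    temporal clustering with PAC-based model selection and spatial template
    sorting, and linear-nonlinear Poisson encoding models with
    cross-validated forward model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
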