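Package: propevo
Title: Reconstructing the Duplication-Fusion-Divergence Origin of
    Beta-Propeller Lectins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for studying how symmetric beta-propeller
    proteins emerge de novo from short tandem-repeated motifs. Provides
    Radar-like internal tandem-repeat detection and internal-identity
    statistics, maximum-likelihood ancestral reconstruction of repeat motifs
    (neighbor-joining trees, Felsenstein pruning, marginal root posteriors and
    the most probable ancestor), combinatorial ancestral-library and
    circular-permutation construct design, a genome-scale molecular-clock test
    of the duplication-fusion-divergence model (Smith-Waterman homology search
    with Karlin-Altschul statistics, clock correlations, and a directionality
    test), and equilibrium-biophysics model fitting (ELISA calibration
    sigmoids, two- and three-state chemical denaturation, thermal melts with
    censoring, and trait correlation/PCA). Ground-truthed simulators for
    sequence families, proteomes, and noisy curves support every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
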