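Package: knockoutr
Title: Robustness of Finite Stochastic Input-Output Maps Under Knockouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and constructing robustness of finite
    stochastic input-output maps (Markov kernels) against knockout of input
    nodes. Implements exclusion dependence (the input-averaged Kullback-Leibler
    deviation of a post-knockout kernel from the unperturbed kernel), its
    conditional-mutual-information lower bound and the optimal post-knockout
    kernel; k-exclusion independence and its neutrality characterisation on
    Hamming-graph connected components of the input support, including the
    mixture construction and its converse decomposition; Gibbs (energy)
    representations of functional modalities with knockout as interaction-term
    removal, Mobius inversion on the subset lattice, gauge normalisation, and
    the exact low-order coefficients that represent k-exclusion independent
    families with interactions of order at most n - k; and identification of
    interaction terms from knockout experiment protocols via log-linear least
    squares with structural identifiability reporting. Includes seeded
    generators for worked example systems and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
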