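Package: rotofit
Title: Bond-Corrected Molecular Geometries and Rotational Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of DFT-optimized molecular geometries for
    rotational spectroscopy. Perceives bonds through Pauling bond orders,
    applies one-parameter core-valence and valence bond-length corrections,
    refits the corrected structure in redundant internal coordinates by
    penalty-function gradient descent, and computes equilibrium and
    (given vibrational and electronic correction inputs) ground-state
    rotational constants, together with benchmark statistics against
    experimental constants for panels of aromatic and heteroaromatic
    molecules of astrochemical interest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
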