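Package: lapfc
Title: Linear-Assignment-Problem Frame Connection for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the frame-connection problem in single-molecule
    localization microscopy (SMLM): combining the repeated per-frame
    localizations of one fluorophore blinking event into a single
    higher-precision localization. Implements a linear-assignment-problem
    formulation with statistically motivated connection, birth, and death
    costs driven by self-calibrated blinking kinetics (on, off, and bleaching
    rates, miss probability) and local emitter density estimates; the
    classical, revised classical, and hypothesis-test baseline connectors; a
    ground-truth blinking simulator with Gillespie and discrete-frame
    kinetics and CRLB-calibrated localization noise; and nearest-neighbor
    distance CDF evaluation statistics against ground-truth ideal
    connections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
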