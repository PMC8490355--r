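Package: porefp
Title: Nanopore Peptide Fingerprinting of Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying proteins from nanopore resistive-pulse
    recordings of their proteolytic digests. Detects peptide blockade events
    in ionic-current traces by threshold search and generalized flat-top
    normal (gNDF) least-squares fitting, computes per-event excluded
    currents, builds and re-aligns excluded-current (I_ex%) spectra,
    calibrates peptide mass to excluded current with a second-order
    polynomial, projects electrospray-ionization mass-spectrometry peak
    tables into predicted spectra, and matches spectra with a squared
    first-derivative Euclidean cosine score under leave-one-out
    classification. Includes an in-silico tryptic digestion engine and a
    synthetic trace simulator with ground truth so the whole pipeline can be
    exercised without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
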