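Package: msrescore
Title: Deep-Learning-Derived Rescoring Features for Peptide-Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes similarity and deviation features that compare
    database-search peptide-spectrum matches (PSMs) against predicted peptide
    properties, and writes them into extended Percolator pin files for
    downstream semi-supervised rescoring. Implements unweighted spectral
    entropy similarity between predicted and experimental MS/MS spectra,
    retention-time calibration by local regression followed by isotonic
    regression with delta-RT features, per-charge ion-mobility calibration,
    and per-bin kernel-density probability features with a uniform prior.
    Includes readers and writers for pin, MGF, mzML and spectral-library
    (msp/TSV) formats, fragment m/z shifting for modifications absent from
    the prediction model, multi-rank DIA processing with experimental peak
    consumption, and a fully seeded synthetic-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
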