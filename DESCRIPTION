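Package: nativems
Title: Charge-State Assignment and Stoichiometry Matching for Native Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the semi-automated analysis of native mass spectra of
    intact protein complexes. Reads two-column m/z-intensity spectra, applies
    Gaussian smoothing, constant/linear/curved background subtraction and
    minimum-intensity filtering, picks peaks inside user-chosen m/z windows,
    and deconvolves consecutive charge-state series into neutral masses by
    variance minimisation over candidate charge assignments (MacSED). Includes
    a mass finder and adjacent-peak prediction for disentangling overlapping
    series, bounded integer enumeration of subunit stoichiometries matching a
    complex mass, a JSON session format recording raw data, processing history
    and assignments for exact replay, a synthetic-spectrum simulator with
    known ground truth, and a command-line interface.
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
    rlang,
    stats,
    tibble,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
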