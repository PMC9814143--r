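Package: lipidoad
Title: Double-Bond Position Annotation of Lipids from OAD-MS/MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves carbon-carbon double-bond (C=C) positions in complex
    lipids from oxygen attachment dissociation (OAD) tandem mass spectra.
    Starting from molecular-species-level annotations (e.g. "PC 18:1_22:6"),
    the package enumerates all theoretically possible double-bond position
    candidates, generates in-silico OAD reference spectra from a formalized
    fragmentation-rule table, verifies the essential diagnostic fragment-ion
    pair for every double bond, and ranks surviving candidates by reverse
    dot-product similarity with square-root-transformed intensities. Includes
    a LIPID MAPS-style shorthand nomenclature parser, MGF/mzML spectrum
    readers, a batch annotation pipeline, and a seeded synthetic-spectrum
    generator with a positive-predictive-value evaluation harness.
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
    readr,
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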