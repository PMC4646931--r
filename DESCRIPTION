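Package: fahfalib
Title: In Silico MS/MS Spectral Libraries and Annotation for FAHFA Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combinatorial enumeration of fatty acid esters of hydroxy fatty
    acids (FAHFAs), rule-based generation of negative-mode collision-induced
    dissociation MS/MS spectra in profiling and fragment-rich acquisition
    modes, reading and writing of NIST MSP spectral libraries and Mascot
    Generic Format (MGF) query files, and automatic annotation of query
    spectra by precursor-window candidate retrieval with forward and reverse
    dot-product scoring. Includes a seeded simulator of noisy query spectra
    so the full annotation pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
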