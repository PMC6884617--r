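Package: glntrace
Title: Stable-Isotope-Resolved Analysis of Glutamine and Glutamate Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope-resolved metabolomics of glutamine and
    glutamate handling in cultured cells. Provides mass-isotopomer-distribution
    (MID) arithmetic with natural-abundance correction by non-negative least
    squares, an atom-mapped steady-state isotopomer simulator for the
    glutamine/glutamate/TCA/proline/fatty-acid network, media-based exchange-rate
    and mass-balance accounting including dual-tracer source apportionment of
    secreted glutamate, isotopomer spectral analysis (ISA) of fatty-acid
    labeling, an untargeted volcano screen with Monte-Carlo power analysis, and
    an end-to-end pipeline runner over tidy tabular inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    pracma,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
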