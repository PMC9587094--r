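Package: padctools
Title: Sequence-Structure-Function Analysis of Phytochrome-Activated
    Diguanylate Cyclases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motif-gated classification of phytochrome-activated diguanylate
    cyclases (PadCs and PadC-EALs), computation of the sensor-effector
    coiled-coil linker-length statistic and its family binning, heptad-repeat
    register calling with an overwinding model for -4 linkers, sequence
    similarity networks from bitscore-thresholded pairwise alignments, and
    distance-based consensus phylogenies with delete-half jackknife support.
    Includes a synthetic-family generator with planted ground truth so the
    whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
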