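Package: helhunt
Title: Detection and Horizontal-Transfer Screening of Non-Autonomous
    Helitron Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates non-autonomous Helitron-family transposable
    elements in DNA sequences and screens them for horizontal transposon
    transfer (HTT). Provides affine-gap local alignment with
    Karlin-Altschul E-value filtering, diagnostic structural annotation
    (5'-TC and 3'-CTRR termini, 3' stem-loop free energy by DNA
    nearest-neighbour rules, inverted repeats, tetranucleotide
    microsatellites), ClustalW-style pairwise and progressive multiple
    alignment, Tamura 3-parameter (+gamma) distances with neighbor
    joining, bootstrap consensus and Robinson-Foulds comparison, a
    comparative-divergence HTT statistic with a permutation test, and a
    synthetic-genome simulator with planted elements and known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
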