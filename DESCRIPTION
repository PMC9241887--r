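Package: microhic
Title: Hi-C Contact-Map Analysis for Small Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for analysing Hi-C chromatin contact
    maps of small (fungal-sized) genomes: binned sparse contact matrices,
    distance-decay curves, random-walk replicate reproducibility,
    insulation-score calling of self-interacting domains (globules),
    distance-stratified binomial significance testing of cis and trans
    contacts with Benjamini-Hochberg FDR, trans-contact centromere calling,
    aggregate chromosome analysis with Rabl-type classification, metric
    multidimensional-scaling 3D genome reconstruction, and position-weight
    matrix motif scanning with exact p-values at domain boundaries. Includes
    a fully parameterised synthetic Hi-C generator with ground truth for
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    methods,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
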