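Package: stagemir
Title: Stage-Resolved Small RNA Profiling for Mosquito Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for developmental small-RNA
    profiling of Anopheles stephensi: adapter trimming, read collapsing and
    length filtering; hierarchical zero-mismatch read classification against
    mature-miRNA, ncRNA, coding and genome catalogs; novel miRNA discovery
    by flank extraction and minimum-free-energy hairpin folding with a
    nearest-neighbor model authored in the package; tags-per-million
    normalization with a conditional binomial exact test and the
    three-criterion regulation filter; miRNA target prediction by perfect
    seed complementarity, intermolecular duplex energy and a
    dinucleotide-shuffle empirical p-value; and degradome (PARE) cleavage
    mapping with T-plots and category 0-4 classification. Ships a seeded
    synthetic-data generator with planted ground truth, plus curated
    fixtures transcribed from the published stage-expression, novel-miRNA
    and degradome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
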