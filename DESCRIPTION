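Package: seqeffort
Title: Sequencing-Effort Planning for Metagenome-Assembled Genome Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plan shotgun metagenome sequencing depth from first principles.
    Models a community metagenome as a weighted population of unique k-mers,
    evaluates the non-uniform coupon-collector integral for the expected
    number of reads to sequence a metagenome to exhaustion, and simulates
    weighted sequencing with replacement to a target fraction of exhaustion.
    A smooth effort surface maps (target fraction, genome size, relative
    abundance) to required bases and inverts a sequencing budget to the
    rarest recoverable genome. Gompertz rarefaction fits relate quality
    metagenome-assembled genome (MAG) yield to sequencing effort under
    MIMAG-style completeness and contamination thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
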