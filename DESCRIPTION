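Package: hepachrom
Title: Chromatin-State Segmentation and Epigenomic Integration for the
    Regenerating Mouse Liver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns chromatin states from binarized epigenomic mark tracks
    with a multivariate Bernoulli-emission hidden Markov model (Baum-Welch
    EM, posterior or Viterbi decoding, BIC state-number selection) and
    integrates the resulting segmentation with gene models, CpG
    methylation, transposable-element age, gene expression, and
    regeneration-timecourse H3K27me3 dynamics. Includes a synthetic
    epigenome generator with known ground truth (Markov-chain state
    sequence, Bernoulli mark emissions, state-conditional expression,
    methylation, and transposable-element catalogues) so the whole
    pipeline is testable end to end, plus resampling statistics for
    transposable-element age and bivalent-promoter clustering utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
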