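Package: covfold
Title: Covariation-Guided Prediction of Possibly Pseudoknotted RNA Secondary Structures from Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts an individual, possibly pseudoknotted secondary
    structure for every sequence of an RNA multiple sequence alignment.
    Column covariation is measured with canonical-pair-restricted mutual
    information and the average product correction; high-scoring
    non-conflicting column pairs and restricted unpaired columns form a
    per-sequence guide structure; a restricted nearest-neighbor free-energy
    minimization then relaxes each guide along four paths and reports the
    lowest-energy structure, allowing density-2 pseudoknots (H-type and
    kissing-hairpin classes). Includes base-pair accuracy metrics
    (sensitivity, PPV, F-measure, and a compatible-pair-adjusted variant),
    a resampling significance test, and synthetic alignment generators
    with planted consensus structures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
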