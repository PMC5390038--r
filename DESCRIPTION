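Package: mwulex
Title: Multi-Word Units in Word Learning and Lexical Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts multi-word units (MWUs) from utterance corpora with an
    incremental chunker driven by backward transitional probabilities (a
    Chunk-Based Learner variant with a frequency-reciprocal noise correction
    and a random-baseline control), derives per-word predictors (#Freq,
    #MWUs, #baseline), estimates word age of first production from child
    transcripts via bootstrap mean length of utterance, and relates
    predictors to age of first production and lexical-decision reaction
    times with full and partial Kendall tau-b correlations and bootstrap
    confidence intervals, including paired-bootstrap intervals for
    differences between coefficients. A synthetic-corpus generator with
    planted collocations and known effect structure makes the whole
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
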