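Package: kptm
Title: Multi-Label Prediction of Lysine Post-Translational Modification Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-label predictors of lysine post-translational
    modification (K-PTM) sites -- acetylation, crotonylation, methylation,
    succinylation and glutarylation -- from protein sequences. Provides
    peptide-window benchmark construction from FASTA plus annotation tables,
    four sequence feature encoders (amino-acid factors, one-hot binary
    encoding, k-spaced amino-acid pair composition, and a sequence-coupling
    encoding built from position-specific conditional probabilities),
    instance-hardness undersampling of the unmodified majority class,
    ANOVA F-statistic feature ranking with incremental feature selection,
    cost-sensitive radial-basis-function support vector machine classifiers
    combined into a multi-label predictor, Chou's five multi-label evaluation
    metrics, and a synthetic-data generator with planted, recoverable motifs
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
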