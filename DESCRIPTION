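Package: igcodon
Title: Interlocus Gene Conversion in Paralog Pairs via Joint Codon Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint two-paralog codon substitution models for quantifying
    interlocus gene conversion (IGC) after a gene or whole-genome
    duplication. Implements Muse-Gaut style F1x4+kappa+omega point-mutation
    rates, a 61^2-state pair process in which each paralog can additionally
    copy the partner's codon at IGC intensity tau, and a generalization that
    splits the nonsynonymous rate factor into homogenizing (omegaH) and
    nonhomogenizing (omegaN) components. Provides maximum-likelihood fitting
    on a rooted species tree with an annotated duplication node,
    likelihood-ratio tests with boundary chi-square mixture nulls, expected
    IGC-versus-point substitution counts per branch via the
    matrix-of-exponentials technique, and an exact event-logged stochastic
    simulator of paralog-pair evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
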