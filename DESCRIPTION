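Package: hibi
Title: Harms Index and Benefits Index for Meta-Analyses with Double-Zero Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures whether trials with zero cases in both arms can alter
    the direction or statistical significance of a meta-analysis of binary
    outcomes. Implements the harms index (Hi) and benefits index (Bi): the
    minimum total number of cases that, when added to the treatment
    (respectively control) arms of the double-zero studies, flips the pooled
    effect's direction or its significance. Provides an exact method that
    enumerates all case-addition combinations up to a per-study cap motivated
    by the rule of three, and a fast approximating method restricted to a
    single pivot study. Pooling engines include the two-stage Peto odds
    ratio (default), the Mantel-Haenszel risk ratio with the
    Greenland-Robins variance, and a one-stage beta-binomial model in which
    double-zero studies are informative. Includes zero-structure subtype
    classification, impact categories, JSON/CSV reporting, iteration plots,
    a seeded synthetic meta-analysis generator, and a batch harness that
    compares the exact and approximating methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
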