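Package: traitcooccur
Title: Trait-Based Inference of Community Assembly from Species Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers community assembly mechanisms (environmental filtering,
    competitive exclusion, neutrality) from species presence-absence data and
    functional traits. Computes pairwise species co-occurrence with the Jaccard
    index, mixed-type Gower dissimilarity over nine trait sets (all traits,
    ecological tolerance and niche groups, and each trait singly), and relates
    the two with a two-step hurdle analysis: a binomial-logit model on binary
    co-occurrence and a linear model on log co-occurrence strength. Includes a
    synthetic community simulator that assembles species pools under filtering,
    limiting-similarity or neutral rules, so slope-sign recovery and type-I
    error calibration of the full pipeline can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
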