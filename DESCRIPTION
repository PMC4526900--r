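Package: honcheck
Title: Automated Detection of HONcode Conformity on Health Websites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains per-criterion naive Bayes detectors for the nine HONcode
    detection criteria (the eight principles of the Health On the Net code of
    conduct, with attribution split into reference and date) from labelled
    compliance extracts, crawls a website (or an offline HTML directory),
    classifies every page or sentence, and aggregates any-of detections into
    site-level verdicts with evidence locations. Ships the five-outcome
    evaluation taxonomy (true/false positives and negatives plus detections on
    a page other than the expert-designated one), its "other"-tolerant
    precision/recall convention, inter-rater agreement statistics (pairwise
    percent agreement and Fleiss' kappa), and a synthetic-data generator for
    corpora, fixture websites and rating matrices so the whole pipeline is
    testable offline.
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
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
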