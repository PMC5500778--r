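Package: adrdist
Title: Distance-Based Filtering of Adverse Drug Reaction Mentions in Patient Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Separates genuine adverse-drug-reaction (ADR) mentions from other
    drug-disorder co-occurrences in patient forum messages using the signed word
    distance between the drug name and the disorder term. Provides lexicon-based
    named entity recognition over MedDRA-style terminologies (LLT/PT/SOC), signed
    word-distance pairing with minimum-distance deduplication, expectation-
    maximization fitting of a univariate Gaussian mixture over distances,
    maximum-a-posteriori cluster assignment with exact decision-boundary interval
    reporting, cluster-merge filtering strategies scored by precision and recall
    against gold annotations, and a synthetic forum-corpus generator for
    end-to-end evaluation without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
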