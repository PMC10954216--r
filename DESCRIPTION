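Package: ridescore
Title: Weighted Skeletal Trait Scoring for Horsemanship Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing habitual horseback riding from human
    skeletal remains using a weighted six-trait scoring system with dual
    classification thresholds (trait count and weighted points) and
    preservation-aware score bounds for traits rendered unobservable by
    taphonomic loss. Ships a transcription of the published Early Bronze
    Age steppe assemblage (24 individuals), assemblage-level demographic
    summaries (masculinity index, subadult fraction), and a synthetic
    skeletal-assemblage generator with Monte-Carlo and exact-enumeration
    evaluation of the diagnostic rule's sensitivity and specificity under
    configurable trait prevalence and preservation loss.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
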