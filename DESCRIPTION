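Package: echopairs
Title: Measurement-Value Pair Extraction from Echocardiogram Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of cardiac structure and function
    measurements from free-text echocardiogram reports and clinic notes.
    Locates mentions of 27 standardized measurement concepts (ejection
    fraction, chamber dimensions, valve gradients, regurgitation and
    stenosis grades, and others) via a custom term dictionary, an
    anatomy/measure word lexicon and a concept-builder that assembles
    unseen term variants, maps mentions to concepts with a two-step
    lookup (exact match, then token-overlap scoring) disambiguated by
    semantic mutual-exclusion constraints, recognizes quantitative and
    qualitative values including ranges and units, and links concepts to
    values through a configurable inventory of co-occurrence patterns.
    Ships a semantic-bootstrapping term harvester for dictionary
    curation, a synthetic report generator with gold annotations, and a
    precision/recall/F1 evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
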