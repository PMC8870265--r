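Package: cveptools
Title: Template Matching and Training-Block Composition Analysis for
    Code-Modulated VEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for code-modulated visual evoked
    potential (cVEP) brain-computer interfaces. Generates and validates
    m-sequence stimulus code sets, derives CCA-based spatial filters,
    classifies multi-channel EEG trials by filter-bank ensemble template
    matching in the style of task-related component analysis (TRCA), and
    evaluates how multi-day training blocks should be composed:
    intra-/inter-session cross-validation, cross-subject transfer grids,
    stepwise-growing models over an interleaved block sequence, and
    reduced-training variants. Includes a seeded synthetic EEG generator
    emulating a two-session, six-block, 32-target recording protocol, a
    plain-text dataset container, and Wolpaw information-transfer-rate
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
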