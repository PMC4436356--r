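Package: mtscreen
Title: Mental-Task Pair Screening for Imagery-Based Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Offline screening analysis for imagery-based brain-computer
    interfaces. Simulates multichannel EEG screening sessions for five mental
    tasks (word association, mental subtraction, spatial navigation, hand and
    feet motor imagery), designs common spatial pattern (CSP) filters in the
    8-30 Hz band, classifies log-normalized variance features with Fisher's
    linear discriminant, ranks task pairs by geometric mean accuracy under
    repeated stratified cross-validation, simulates between-day model
    transfer with bias-only classifier re-adaptation, and compares pair
    rankings with Friedman and Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
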