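Package: vocalinfo
Title: Cross-Validated MANOVA Decoding of Vocalization Content and
    Production from MEG Epochs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating time-resolved neural information about the
    content (vowel identity) and production form (overt versus covert) of
    human vocalization from multichannel magnetoencephalography epochs.
    Implements cross-validated MANOVA pattern distinctness with cross-time,
    cross-variable, split-condition and cross-session generalization, the
    expected-cross-information benchmark for representational overlap,
    searchlight source mapping with a lateralization index, delay-window
    group statistics with false-discovery-rate control, and a forward
    simulator of the rule-based vocalization task that plants known
    representational structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'methods-EpochArray.R'
    'task_design.R'
    'source_space.R'
    'effects.R'
    'simulate.R'
    'preprocess.R'
    'contrasts.R'
    'cvmanova.R'
    'source_analysis.R'
    'group_stats.R'
    'pipeline.R'
    'io.R'
    'vocalinfo-package.R'
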