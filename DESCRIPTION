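Package: habslope
Title: Habituation Slope Analysis for fMRI Repetition Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring neural habituation from repetition-task fMRI:
    a synthetic-cohort generator for repetition-suppression BOLD time-series
    with known ground truth, ART-style artifact detection and run exclusion,
    nuisance residualization and ROI/hemisphere averaging, data-driven
    habituation-window detection, novelty-normalized habituation slopes (b'),
    and longitudinal group inference with linear mixed models, one-sample
    habituation tests, effect sizes, and familywise-corrected clinical
    correlation screens.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
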