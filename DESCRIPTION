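Package: textrecal
Title: Simulation and Decoding Analysis of Text-Based Phonetic
    Recalibration fMRI Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for text-based phonetic recalibration experiments, in
    which written text paired with ambiguous speech shifts the perceptual
    /aba/-/ada/ category boundary. Provides generators for the factorial
    psychophysical and event-related fMRI session designs, simulators for
    binary categorization behavior (logistic mixed model) and multivoxel
    BOLD time series on a cortical-sheet surrogate, logistic mixed-effects
    psychometric analysis, single-trial double-gamma hemodynamic beta
    estimation with per-vertex time-to-peak adjustment, a balanced-resampling
    recursive-feature-elimination support-vector percept decoder with
    permutation statistics and group consistency maps, and
    psychophysiological-interaction connectivity analysis with Monte Carlo
    cluster-size correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    e1071,
    RNifti,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
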