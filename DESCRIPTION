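Package: vigistate
Title: Resting-State EEG Vigilance Staging and Arousal Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing brain-arousal regulation in twenty-minute
    eyes-closed resting-state EEG. One-second epochs are classified into the
    seven vigilance stages of the Leipzig vigilance ladder (0, A1, A2, A3, B1,
    B2/3, C) from regional band powers, slow-eye-movement evidence and
    spindle/K-complex markers; from the resulting stage sequence the package
    computes per-minute and total stage amounts, mean vigilance values, the
    1-14 arousal stability score, and prototype arousal-regulation types
    assigned by least squared deviation. A cohort layer provides the matching
    nonparametric statistics (one-tailed Mann-Whitney U with exact small-sample
    p-values, chi-square on prototype frequencies, Spearman correlations,
    median-split subgrouping) and a synthetic-data module generates stage
    trajectories, multichannel EEG/EOG signals and covariate tables with known
    ground truth so the entire chain is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
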