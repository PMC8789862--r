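Package: scalphfo
Title: Scalp EEG High-Frequency Oscillation Detection and Surgical Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated detection of high-frequency oscillations (HFO, ripple
    band 80-250 Hz) in scalp EEG using a three-stage Stockwell-transform
    detector, with per-channel rate estimation, the double-percentile "HFO
    area" statistic, electrode-to-craniotomy-defect geometry on a spherical
    10-20 head model, and the outcome-prediction statistics used to relate
    HFO rates to postsurgical seizure freedom (Spearman correlation,
    zero-discarding Wilcoxon signed-rank, ROC operating-point threshold with
    two-fold cross-validation, predictive values). Includes a seeded
    synthetic-cohort generator that emulates pediatric pre/post epilepsy
    surgery recordings so the full pipeline is testable without patient
    data, and minimal European Data Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
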