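Package: socgaze
Title: Eye-Tracking Measures of Social Salience and Social Value
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for two complementary eye-tracking measures of
    social reward processing: the global-effect (center-of-gravity) paradigm,
    in which the signed deviation of the first saccade toward a peripheral
    social image indexes social salience, and the preferential-looking
    (freeview) paradigm, in which the proportion of dwell time on a social
    versus a paired nonsocial image indexes social value.  Includes raw gaze
    ingestion (CSV and EyeLink-ASC-like text), velocity/acceleration saccade
    and fixation parsing with blink handling, per-trial deviation-angle and
    dwell-proportion metrics with latency and capture-rate exclusion rules,
    stimulus-matching metrics (global and local RMS contrast, grid
    scrambling, paired ratio tests), an inferential layer (one-sample and
    paired t tests with Cohen's d, Pearson correlations, Steiger's Z for
    dependent correlations, Cousineau within-subject error bars), and a
    synthetic 500 Hz gaze-stream generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
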