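Package: bfrsprint
Title: Repeated-Sprint Exercise Analysis Under Blood Flow Restriction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for repeated cycling sprint tests to
    exhaustion performed under partial vascular occlusion (blood flow
    restriction). Processes near-infrared spectroscopy (NIRS) oxygenation
    signals with zero-phase low-pass filtering, automatic sprint
    segmentation, per-sprint delta extraction and set-duration
    normalisation; computes sprint performance endpoints (fatigue index,
    total work, 30-s peak oxygen uptake, pulse-oximetry summaries) and
    neuromuscular fatigue metrics from evoked force and surface EMG
    (voluntary activation by the interpolated-twitch technique,
    low-frequency fatigue ratios, EMG RMS normalised to the M-wave);
    performs linear mixed-effects inference with likelihood-ratio tests
    and Tukey-adjusted least-squares-means contrasts. A synthetic study
    generator with stored ground truth emulates the full recording
    protocol so every stage is testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
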