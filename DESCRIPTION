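Package: microsacc
Title: Binocular Microsaccade Detection and Pre/Post Session Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects microsaccades in binocular gaze recordings with the
    median-based velocity-threshold algorithm (elliptic threshold, minimum
    duration criterion, greedy binocular pairing), and analyses per-trial
    event counts from pre/post intervention fixation sessions: per-second
    rates, paired t-test, Cohen's d (pooled, single-group and
    difference-score variants), pre/post stability correlation, per-trial
    timecourses, detection-parameter effect-size surfaces and bootstrap
    trial-count sensitivity curves. Includes a seeded binocular gaze
    simulator (mean-reverting drift, raised-cosine microsaccade waveforms on
    a linear main sequence, refractory event process, per-eye sensor noise,
    blinks) with ground truth, so the whole pipeline is testable without
    recorded data, plus tab-separated readers/writers for sample and event
    tables and pixel-to-degree conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
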