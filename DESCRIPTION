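Package: nwreflex
Title: Quantification of the Nociceptive Withdrawal Reflex from EMG and
    Endpoint Force Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stimulus-locked analysis of the human upper-limb nociceptive
    withdrawal reflex. Provides trial epoching of multi-channel surface EMG
    and six degree-of-freedom wrist force/moment recordings around electrical
    stimulus trains; the standard reflex EMG chain (DC-offset removal,
    rectification, baseline statistics and 3-SD threshold onset detection,
    onset-to-offset mean-EMG quantification, eight-trial condition averages);
    planar endpoint force-vector extraction (per-axis local peaks, resultant
    magnitude and direction); the statistical layer used for joint-position
    and motor-practice comparisons (repeated-measures ANOVA with subject as a
    random factor, Bonferroni-adjusted post hocs, paired and independent
    t-tests, percent-change and latency-change contrasts); and a fully
    seeded synthetic-recording generator with ground truth for parameter
    recovery and type-I error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
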