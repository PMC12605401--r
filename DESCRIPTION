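Package: ethoscore
Title: Automated Behavior Classification and Recognition-Memory Scoring from Markerless Pose Tracks
Version: 0.1.0
Authors@R: person("Ethoscore", "Developers", email = "ethoscore@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for markerless pose-estimation output from
    rodent three-chamber social-interaction sessions: confidence-based frame
    gating with snout-to-mid-body fallback, zone-based per-frame classification
    of sniffing and rearing at each conspecific cage, categorical label
    smoothing, bout extraction, interaction times, discrimination indices
    (per-trial, cumulative, per-minute running, trial-block and early-window
    variants with saturation exclusions), closed-form small-sample statistics
    (one-sample t, Pearson correlation, simple regression), and a synthetic
    trajectory and exploration-table generator with known ground truth so every
    stage is testable without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
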