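Package: lidlfp
Title: Spectral, Phase-Coupling and Behavioral Analysis of Levodopa-Induced
    Dyskinesia Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for characterizing levodopa-induced dyskinesia
    (LID) and antidyskinetic drug effects from multichannel local field
    potential (LFP) recordings and pose-tracked behavior. Implements bipolar
    LFP derivation, spectrograms with irregular-resampling (IRASA) separation
    of oscillatory and aperiodic spectral components, parametric narrowband
    gamma (NBG) peak detection with printed detection thresholds, phase-based
    functional connectivity as the von Mises concentration of instantaneous
    phase differences between structures, whole-spectrum brain-state
    correlation across treatments, rotational-behavior quantification from
    pose-tracking tables, and abnormal-involuntary-movement (AIMs) score
    aggregation. A synthetic-data generator with full ground truth (1/f
    backgrounds, scheduled narrowband oscillations, controlled phase coupling,
    drug-response time courses, rotation trajectories and AIMs schedules)
    exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
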