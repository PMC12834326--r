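Package: epimon
Title: Analysis Toolkit for DC-Sensitive Multimodal Rodent Epilepsy Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads and writes the hourly binary telemetry format of a
    DC-sensitive rodent epilepsy monitoring rig (a 4096-byte header followed
    by 63-byte packets carrying two 8-channel 24-bit biopotential front ends
    and a tri-axis accelerometer), converts raw codes to physical units, and
    provides the offline analysis stack: zero-phase filtering and Welch
    spectral estimation, spreading-depolarization detection on DC-coupled
    traces, seizure counting, R-peak/RR-interval extraction, vigilance-state
    scoring from hippocampal rhythms and head acceleration, constant-potential
    amperometry oxygen calibration and in vivo post-processing, and a
    video/electrophysiology synchronization check based on actigraphy
    cross-correlation. A seeded multimodal session simulator with a
    ground-truth event ledger supports end-to-end validation of every
    detector without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    graphics,
    grDevices
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
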