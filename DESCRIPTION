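Package: vdrnscreen
Title: Screening for Vitamin D-Responsive Neurons in Stimulus-Locked
    Calcium Imaging and Nucleated-Patch Recordings
Version: 0.1.0
Authors@R:
    person("H.", "Mercer", email = "hmercer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying drug-responsive neurons from
    stimulus-locked wide-field calcium imaging, together with voltage-clamp
    sweep analysis of high-voltage-activated calcium currents. Implements the
    instantaneous delta-F/F statistic for alternating unstimulated/stimulated
    frame pairs, rolling-ball background subtraction, translational image
    registration, baseline detrending with a k-standard-deviation responder
    criterion, z-drift quality control, P/N leak subtraction, current-voltage
    curve extraction, drug-response time-course classification, and Welch
    t-test group reporting. A seeded synthetic-data generator emulates both
    modalities with full ground truth so every stage is testable without any
    acquisition hardware or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
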