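Package: pwavetools
Title: P Wave Analysis of 12-Lead ECGs for Atrial Fibrillation Ablation Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting P wave parameters from digitised 12-lead
    electrocardiograms and relating them to pulmonary vein isolation outcomes.
    Provides a synthetic 12-lead ECG generator with ground-truth fiducials,
    a Bessel bandpass and mains-notch preprocessing chain, chord-distance
    P wave delineation with file-based manual overrides, computation of
    P wave duration (raw and Hodges rate-corrected), voltage, area,
    dispersion, terminal force in V1 and inter-atrial block classification,
    and a cohort statistics layer (normality-gated two-sample tests,
    categorical tests, univariable Cox hazard ratios, intraobserver
    variability) producing per-lead comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
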