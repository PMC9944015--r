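Package: cbctdose
Title: Patient Dose Monitoring for Dental Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dose-audit pipeline for dental cone-beam computed tomography
    (CBCT) exposure logs. Reads DICOM-header-style exposure records, derives
    and applies quality-control based dose-area-product (DAP) correction
    factors, converts tube-loading based effective dose conversion factors
    (uSv/mAs) into DAP-based factors (uSv/dGy.cm2) per device and age group,
    computes per-examination and collective effective doses, and produces
    stratified summary tables (age group, field-of-view category, operation
    mode, clinical indication) with normal-approximation confidence
    intervals. Includes a synthetic cohort generator emulating fixed-protocol
    and tube-current-modulated scanners so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
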