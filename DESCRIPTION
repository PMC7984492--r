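Package: chartcheckr
Title: Automated Initial Chart Check for Photon/Electron External-Beam Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tolerance-driven comparison of treatment-planning-system (TPS)
    plan exports against their record-and-verify (OIS) counterparts for
    external-beam radiotherapy, plus the bespoke rule checks of an automated
    pretreatment physics chart review (fractionation arithmetic, isocenter
    geometry, CT Hounsfield-unit screening, hotspot detection, couch-shift
    policy and more). Includes a checklist data model for TG-275/TG-315 style
    check items with FMEA risk attributes and per-scenario automation
    feasibility classes, and a benefit simulator that estimates residual
    manual check time and residual detectable-error percentages under
    different levels of chart-check automation. A deterministic synthetic
    fixture generator produces paired TPS/OIS plan snapshots (JSON and DICOM
    RT Plan), CT phantoms and dose grids with a manifest-recorded injected
    error taxonomy, so the whole battery is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
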