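Package: fcpoct
Title: Point-Wise Structure-Function Analysis of Fundus-Controlled
    Perimetry and OCT in Non-Exudative AMD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially resolved structure-function analysis for
    non-exudative age-related macular degeneration. Registers
    fundus-controlled perimetry (microperimetry) stimulus grids to OCT
    en-face retinal layer thickness maps via landmark correspondences,
    samples per-stimulus layer thicknesses and structural biomarker
    presence, normalizes sensitivities and thicknesses against a control
    cohort (point-wise deviations and z-scores), and fits cross-sectional
    and inter-visit linear mixed-effect association models with patient,
    visit and grid-point random intercepts. Includes a reproducible
    synthetic cohort generator encoding the published effect structure so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
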