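Package: connlsm
Title: Connectome-Based Lesion-Symptom Mapping for Stroke Aphasia
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mass-univariate permutation-thresholded general linear models
    relating region-based lesion damage, structural-connectome fiber counts,
    and resting-state functional-connectome edges to aphasia severity scores.
    Includes the nuisance-regression schemes used in connectome-based
    lesion-symptom studies (total lesion volume, per-edge structural
    residualization of functional connectivity, critical-area lesion load),
    resting-state preprocessing (nuisance detrending, band-pass filtering,
    lesion-overlap filtering of independent components, Pearson connectome
    construction), and a synthetic stroke-cohort generator so that every
    stage is testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
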