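Package: simsquant
Title: Quantitative ToF-SIMS Depth Profiling and 3D Ion-Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of time-of-flight secondary ion
    mass spectrometry (ToF-SIMS) measurements of chlorinated additives in
    polymer matrices, developed around insecticide-incorporated bed-net
    fibers. Implements relative sensitivity factor (RSF) calibration from
    ion-implanted standards, detection-limit estimation, conversion of
    per-cycle ion counts into concentration-versus-depth profiles, chlorine
    density to analyte weight-percent conversion, descriptive statistics of
    normalized surface intensity ratios across wash/regeneration conditions,
    and 3D ion-image analysis: intensity histograms, size-biased contribution
    distributions and their log-logistic fits, threshold fraction queries,
    and connected-component segmentation of high-intensity domains with
    physical-unit morphology. A synthetic-data module generates implant
    profiles, intensity cubes with planted ellipsoidal domains, wash series,
    and patchy surface maps so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
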