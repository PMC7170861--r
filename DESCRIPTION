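Package: chemotaxkit
Title: Quantification of Leukocyte Chemotaxis, Polarization and
    Lipid-Binding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for common readouts of leukocyte
    directed-migration experiments: time-lapse track statistics
    (velocity along the path, directional meandering index, volume and
    path-length exclusion filters, analysis-window selection),
    front-rear polarization of segmented single cells (centroid-based
    polarization index, moment-ellipse aspect-ratio gating),
    membrane-biosensor front-ratio time series, transwell
    transmigration indices, steady-state surface plasmon resonance
    isotherm fitting (Req = Rmax/(1 + KD/C)), vesicle-sedimentation
    fraction bound, and kinase fold-activity normalization. Seeded
    synthetic-data generators emulate the statistical structure of each
    assay so the full pipeline is testable without microscope or
    biosensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
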