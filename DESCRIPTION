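Package: ehtkit
Title: Functional Analysis of Engineered Heart Tissue
Version: 0.1.0
Authors@R:
    person("EHT", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for engineered human heart tissue ("cardiopatch")
    functional characterization: optical-mapping electrophysiology (activation
    maps, isochrones, conduction velocity, APD80, arrhythmia episode
    classification, graft-host coupling), isometric contractile mechanics
    (twitch kinetics, force-length relationships, passive stiffness, specific
    force, force-frequency relationship), intravital vascularization
    quantification (hyperspectral Beer-Lambert hemoglobin unmixing, CLAHE
    contrast enhancement, vessel segmentation, blood vessel density), GCaMP
    calcium transient dF/F analysis, and scalar quantification calculators
    (morphometry, delta-delta-Ct expression, densitometry). Includes
    ground-truth-known synthetic data generators for every pipeline stage, a
    file-format layer (CSV movies and traces with JSON sidecars), and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
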