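Package: gliomotion
Title: Collective Motion, Shape and Border Analysis for Glioma Cell Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify collective migration of glioma cells from
    time-lapse tracking data and histology-derived masks. Classifies the
    heading distribution of a tumor zone as swarm (uniform), stream
    (bimodal-antipodal) or flock (unimodal) by maximum-likelihood fits of
    circular distributions compared through Akaike weights; computes
    per-step kinematics, pair directional correlations, relative-position
    maps and nearest-neighbour statistics; measures nuclear shape
    descriptors (aspect ratio, circularity, Feret angle) and nematic
    alignment from labeled masks; extracts smoothed tumor-brain interfaces
    by Allen-Cahn phase-field evolution and measures their sinuosity; and
    provides seeded synthetic-data generators with ground truth for every
    estimator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    xml2,
    yaml,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
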