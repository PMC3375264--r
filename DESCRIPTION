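Package: gazeflow
Title: Analytic Optic Flow and Flow-Derivative Signatures Under Active Gaze Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling of instantaneous optic flow for a pinhole
    camera under passive self-motion and under gaze-stabilizing (fixating)
    self-motion, with analytic ray-cast depth maps for synthetic scenes
    (ground plane, box posts, cylindrical pillars). Flow Jacobians are
    decomposed into divergence, curl and the two shear components, with
    closed-form expressions for tilted planes, gaze-parallel planes,
    cylindrical edges and apical edges, a Schwartz-type monopole mapping to a
    cortical coordinate frame, a biologically inspired center-surround
    derivative operator bank, and flow-discontinuity based segmentation of
    obstacles. Includes Middlebury .flo input/output for externally computed
    flow fields.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
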