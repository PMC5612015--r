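Package: ribxromm
Title: Rib Kinematics from Marker-Based X-Ray Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying rib rotation during breathing from
    marker-based biplanar videoradiography (XROMM) data. Estimates per-frame
    rigid-body poses of vertebrae, rib segments and sternum from 3D marker
    trajectories by orthogonal Procrustes fitting, screens intermarker
    distances to decide rigid versus mobile versus bending elements, attaches
    anatomical joint coordinate systems and extracts intrinsic ZYX Euler
    angles (bucket handle, calliper and pump handle motion), normalizes
    breath cycles to 100 phase points, and compares the in vivo axis of total
    rib rotation (axis-angle decomposition of the peak-inhalation to
    peak-exhalation rotation) against the hinge axis predicted from the
    vertebral parapophysis and diapophysis landmarks. Includes a ground-truthed
    synthetic ribcage simulator emulating a tripartite crocodylian ribcage for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
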