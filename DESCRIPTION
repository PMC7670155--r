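Package: acromion3d
Title: Three-Dimensional Acromial Morphometry from Labeled Shoulder Bone Meshes
Version: 0.1.0
Authors@R: person("Morphometrics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Landmark-based scapular coordinate frames and eight acromial shape
    parameters measured on labeled shoulder bone surface meshes: the
    acromiohumeral interval (AHI), acromial anterior and inferior protrusion
    (AAP, AIP), the acromioclavicular angle, and the width and anteroposterior
    extent of the acromial anterolateral protrusion (AALP) localized by
    contour-curvature crease detection on axial mesh slices. Includes a
    parametric synthetic shoulder generator with closed-form ground truth,
    rater-noise and cohort simulators, reliability statistics (CV%, ICC%),
    three-group comparisons (one-way ANOVA, Welch pairwise tests, percent
    differences) and 95% reference ranges, plus mesh/landmark I/O and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
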