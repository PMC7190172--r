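Package: coregkit
Title: Automated MEG-MRI Co-Registration and Inter-Method Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for aligning magnetoencephalography (MEG) digitization
    data with an MRI-derived scalp surface. Implements a five-step automated
    co-registration pipeline (template landmark transfer, landmark-based
    rigid initialization, iterative closest points against the triangulated
    scalp surface, outlier rejection, final refinement), the median
    point-to-surface co-registration error metric, rigid-transform
    decomposition into translations and pitch/roll/yaw, and an inter-method
    reliability analysis based on the intra-class correlation ICC(3,1).
    Includes a synthetic head-cohort generator (parametric scalp surfaces
    with labeled fiducials, digitizer noise, and a simulated manual
    operator) so manual-versus-automated comparisons can be reproduced at
    desk scale with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
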