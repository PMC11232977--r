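Package: krillcam
Title: Volumetric Prey Density from Single-Camera Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates volumetric prey density (animals per cubic metre) and
    biomass density from object annotations made on single-camera 2D imagery,
    such as frames from animal-borne video loggers deployed on foraging
    predators. The resolvable range of the camera is estimated from the size
    distribution of resolvable versus unresolvable imaged objects via a
    logistic decision boundary, converted to a pyramidal imaged volume using
    the camera field of view and a reference prey-length distribution, and
    propagated to per-image densities with discrete-grid sensitivity analysis
    and Monte-Carlo error propagation of the boundary uncertainty. Includes a
    forward simulator of prey swarms in the camera frustum with known ground
    truth, confusion-matrix evaluation metrics for frame classifiers, and
    readers for VIAME-style annotation exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
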