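Package: locomorph
Title: Two-Dimensional Geometric Morphometrics and Locomotor-Ecology
    Classification for Skeletal Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional landmark-based geometric morphometrics
    of skeletal elements (astragali and pedal unguals in particular):
    reading and writing TPS landmark files and slider tables, resampling
    digitized open curves to fixed semilandmark counts, generalized
    Procrustes analysis with sliding semilandmarks under bending-energy or
    Procrustes-distance criteria, thin-plate-spline warps and deformation
    grids, covariance-matrix principal component analysis of tangent-space
    shape coordinates and of log10 linear measurements, and an iterative
    PC-prefix binomial logistic regression search (AIC-selected) that
    assigns unlabelled specimens a probability of arboreal/scansorial
    versus terrestrial/bipedal-saltating locomotor ecology. A synthetic
    data module generates landmark and measurement datasets with known
    class structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
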