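Package: aerialpheno
Title: Plot-Level Trait Extraction from UAV Point Clouds and Orthomosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An aerial-phenotyping toolkit for gridded field trials. From
    per-date 3D point clouds and RGB orthomosaics it builds terrain-corrected
    canopy height models (statistical outlier removal, cloth-simulation ground
    filtering, TIN rasterization, slope-plane removal), aligns height and
    colour imagery with a four-point perspective transform, segments labelled
    plot masks with ISODATA thresholding and Hough line detection, and
    measures plot-level static traits (percentile canopy heights, seedling
    counts, canopy coverage, RGB vegetative indices, GLCM texture). Multi-date
    trait series are fitted with offset Gaussian growth curves from which
    dynamic phenotypes are derived: the rapid growth phase between the curve's
    inflection days, fastest and average growth rates, peak-trait day, and the
    beginning of ripening from a normalized-curvature curve. A synthetic-field
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    FNN,
    interp,
    png,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
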