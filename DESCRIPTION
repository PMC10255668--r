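Package: thermomap3d
Title: 3D Thermographic Mapping of Residual Limbs from 2D Infrared Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Registers sets of 2D infrared thermography images onto a 3D
    surface mesh of a transtibial residual limb and recovers per-vertex skin
    temperatures. Implements the full workflow: anchored jet colormap
    encoding of thermal rasters, inversion of the colormap with a grown
    radial-basis interpolator, planar-target camera calibration with radial
    distortion, fiducial-cube pose initialization refined by mutual
    information, best-view/blended per-vertex texturing, colour-to-temperature
    conversion, differential (post-walk minus rest) 3D maps, and intrinsic
    registration-accuracy assessment from near-zero-difference halos around
    thermal fiducial markers. A synthetic-scene generator (parametric limb
    mesh, cube fiducials, Gaussian hot spots, distorted pinhole renderer with
    sensor noise) makes every stage testable without camera hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    minpack.lm,
    igraph,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
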