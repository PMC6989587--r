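Package: rbcmech
Title: Erythrocyte Membrane Mechanics from Capillary Plug-Flow Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates red-blood-cell membrane mechanical properties from
    high-frame-rate time-lapse microscopy of capillary plug flow. The
    pipeline segments dark cells on a bright background, traces and
    resamples closed membrane contours, estimates discrete
    deformation-gradient tensors between consecutive frames by
    spline-weighted cluster least squares, solves the discretized
    Navier-Cauchy equations pointwise for the Lame constants via the
    Moore-Penrose pseudoinverse, and derives Young's and bulk moduli, wall
    shear stress and membrane tension along the membrane. A PCA model
    built from baseline cells separates mechanically distinct
    subpopulations by a 3-standard-deviation rule. A synthetic-scene
    module renders plug-flow image stacks, affine contour sequences and
    manufactured elastodynamic fields with known ground truth so that
    every stage is verifiable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    EBImage,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
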