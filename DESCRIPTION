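Package: gvbuckle
Title: Sonomechanical Buckling of Gas Vesicles by Thin-Shell Finite Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the pressure-driven buckling of gas vesicles (GVs),
    gas-filled protein nanostructures used as acoustic contrast agents and
    reporter genes. Builds parametric capsule meshes (cylinder with conical
    end caps), assembles an orthotropic thin-shell finite-element model
    (constant-strain membrane plus rotation-free hinge bending), and computes
    linear buckling thresholds and modal frequencies by sparse eigenanalysis.
    An explicit central-difference integrator simulates the response to a
    tapered ultrasound sine burst with isothermal trapped-gas back-pressure
    and bulk-viscosity damping; a ramp-plus-bisection search locates the
    dynamic buckling threshold from the volume-change trajectory. Geometry
    sweeps with power-law fits quantify how the threshold scales with
    diameter and length, and a synthetic population module reproduces
    hydrostatic precollapse selection and nonlinear-signal onset at the
    ensemble level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RSpectra,
    minpack.lm,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
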