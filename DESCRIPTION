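Package: elastocg
Title: Coarse-Grained Elastohydrodynamics of Filaments and Sphere-Built Bodies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates collections of three-dimensional inextensible Kirchhoff
    filaments (bend and twist) and rigid bodies built from spheres, coupled
    non-locally through Rotne-Prager-Yamakawa (RPY) Stokes-flow hydrodynamics.
    Momentum balance is integrated over rigid sphere-built segments, turning
    the elastohydrodynamic boundary-value problem into a stiff ODE system for
    body positions and segment orientations. Rotations are tracked with the
    exponential map of quaternions (with singularity rescaling) or with a
    direct quaternion backend for cross-validation. Includes scenario builders
    and measurements for filament relaxation, helical actuation, undulatory
    swimmers, a bi-flagellate puller swimmer, sperm-egg scattering and ciliary
    tracer transport, plus a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
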