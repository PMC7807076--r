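Package: tracheoseed
Title: Hydrodynamics and Perfusion Cell-Seeding Simulation for Rotating
    Tubular-Scaffold Bioreactors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of the hydrodynamic environment and
    perfusion cell seeding of a rotating tubular-scaffold (tracheal)
    bioreactor. Computes steady laminar flow in the scaffold lumen as a
    reduced-order composite of Poiseuille through-flow and a developing
    azimuthal swirl field for two fluid-delivery designs (single rotating
    inlet, double static inlet), maps luminal wall shear stress, tracks
    cell-sized particles with Stokes drag, gravitational settling and
    centrifugal slip to a trapped/escaped/incomplete fate, bins deposition
    into density-fraction maps with uniformity metrics, and emulates a
    bio-punch cell-count validation experiment with overdispersed
    (negative-binomial) counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
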