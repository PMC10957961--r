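Package: haemosph
Title: Weakly Compressible SPH Fluid-Structure Interaction for Heart-Valve
    Haemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale weakly compressible smoothed particle hydrodynamics
    (WCSPH) solver for cardiovascular flows, with two-way fluid-structure
    interaction for rigid hinged leaflets (bi-leaflet mechanical heart valves)
    and for flexible elastic leaflets via a total-Lagrangian SPH scheme.
    Includes dynamic boundary condition walls, open inlet/outlet buffer zones
    with ghost-point extrapolation, a Smagorinsky sub-particle-scale turbulence
    closure, and SPH-side estimation of wall shear stress together with the
    derived haemodynamic risk metrics TAWSS, OSI, ECAP, PSWSS and effective
    orifice area.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
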