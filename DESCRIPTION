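Package: aeroscatter
Title: Polarimetric Radar Cross Sections of Airborne Organisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electromagnetic modeling toolkit for radar aeroecology. Computes
    full solid-angle, dual-polarization radar cross sections (RCS) of airborne
    organisms from triangulated body meshes or parametric ellipsoids with a
    homogenized complex permittivity, using a method-of-moments solution of the
    volume electric-field integral equation (coupled-dipole formulation).
    Includes Mie-series reference solutions for dielectric and conducting
    spheres, radar-facing polarimetric analytics (differential RCS,
    simultaneous-transmit emulation, sector statistics, size-ratio analysis),
    and an emulation of controlled RCS measurement with a vector network
    analyzer (synthetic frequency sweeps, time gating, substitution
    calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
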