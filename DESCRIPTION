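Package: scrollwave
Title: Scroll-Wave Unpinning by Electric Fields in 3D Excitable Media
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the Barkley reaction-diffusion model on a 3D grid
    with a spherical non-excitable obstacle embedded by the phase-field
    method, couples the medium to pulsed-DC, AC and circularly polarized
    external electric fields through a Neumann boundary condition at the
    obstacle surface, and provides the analysis pipeline (probe-based
    wave-frequency measurement, scroll-wave filament detection,
    unpinning and removal classification, parameter-region scans) used
    to study wave emission from heterogeneities and the removal of
    pinned scroll waves by a circularly polarized field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
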