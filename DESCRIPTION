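Package: turingbuds
Title: Sequential Masked Turing Reaction-Diffusion Simulation of Feather
    Bud Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the sequential emergence of feather primordia as a
    series of two-species Schnakenberg reaction-diffusion (Turing) systems
    run one after another on a rectangular skin domain.  Each system's
    kinetics are gated by a binary competence mask so that new condensations
    can only form in tissue not yet patterned by earlier systems; morphogens
    still diffuse everywhere.  Provides linear stability analysis
    (dispersion relation, critical diffusion ratio, fastest-growing
    wavenumber), a semi-implicit finite-difference solver with periodic and
    zero-flux boundaries, competence-mask construction including a horseshoe
    geometry, scenario orchestration (full sequence, second-bud removal,
    horseshoe confinement), detection and spatial classification of
    activator condensations relative to the primary bud, and seeded
    synthetic fixtures for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
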