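Package: protonmotor
Title: Proton-Transfer-Coupled Rotation of the ATP Synthase c-Ring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-coordinate hybrid Monte Carlo/Langevin simulator of the
    membrane-embedded Fo motor of ATP synthase (a-subunit plus c10-ring),
    with per-subunit glutamate-to-aspartate mutation support. Protonation
    states of the ten c-ring carboxylates and the two a-subunit relay
    glutamates are updated by Metropolis Monte Carlo under a pH gradient and
    membrane potential, and the ring angle evolves by overdamped Langevin
    dynamics on the same energy surface. Includes trajectory observables
    (last-return rotational velocity, proton flux, per-subunit stage-duration
    decomposition, uptake-duration sharing), a biochemical data-reduction
    pipeline (luciferase slopes and calibration, ACMA quench, DCCD
    sensitivity, expression normalization, error propagation, pooled t-tests
    from summary statistics, distance-activity regression), and seeded
    synthetic-data generators for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
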