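Package: hbkr
Title: Stochastic Reaction-Diffusion Modelling of Hunchback-Kruppel Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dual regulation of the Drosophila gap gene hunchback (hb)
    by Kruppel (Kr) during mid nuclear cleavage cycle 14, on a one- or
    two-dimensional lattice of nuclear subvolumes. Provides a mean-field
    (mass-action ODE, fixed-step fourth-order Runge-Kutta) solver and an exact
    stochastic reaction-diffusion master equation sampler (next-subvolume
    method), mechanism variants (Kr dual, Hb dual, dual-dual, mutual
    inhibition, static Kr, Kr null), and an analysis layer for boundary and
    peak positions, between-replicate positional variability, and
    within-nucleus two-locus transcript noise.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
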