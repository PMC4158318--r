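Package: mtbuckle
Title: Variational Buckling Analysis of Microtubules as Nonlocal Orthotropic Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the buckling analysis of microtubules modelled as
    orthotropic cylindrical shells with Eringen-type nonlocal constitutive
    relations and an elastic filament-network foundation. Provides an exact
    symbolic engine (a jet-space polynomial algebra) that verifies the
    variational formulation of the governing equations, a Rayleigh-Ritz
    solver for critical axial buckling loads with an independent
    Galerkin-on-PDE cross-check, evaluation of the natural and geometric
    boundary conditions at the shell ends, and a small configuration-driven
    command-line interface for verification runs, buckling-load tables and
    parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
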