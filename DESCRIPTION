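Package: sopes
Title: Sum-of-Products Potential Energy Surfaces by Reparametrization and
    Multigrid Tensor Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building grid-based sum-of-products (Tucker form)
    molecular potential energy surfaces from a parametrized energy backend.
    Reparametrizes the backend against reference energies and harmonic
    frequencies by weighted least squares with derivative-free global
    (multistart single-linkage) and local (BOBYQA) bound-constrained
    optimization; generates staged reference-geometry sets (displacement
    grids, random full-dimensional points, interpolated reaction paths and
    distortion clouds); tensor-decomposes the resulting surface with exact
    POTFIT or the Multigrid POTFIT algorithm using coarse and partial grids
    only; and validates surfaces via harmonic analysis, velocity-Verlet
    classical trajectories, and dense low-dimensional discrete variable
    representation vibrational eigensolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nloptr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
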