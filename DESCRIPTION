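Package: cellgrain
Title: Multiscale Mechanics of Cell Populations: Discrete Models and
    Their Continuum Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating populations of biological cells with
    off-lattice center-based and vertex-based mechanical models, for
    coarse-graining the intercellular forces into macroscopic pressure
    laws using regular-polygon and polyhedron geometry factors, and for
    solving the resulting nonlinear density-transport equation with a
    mass-conservative finite-volume method.  Provides bounded Voronoi
    tessellation of cell centers in one and two dimensions, exponential
    and polynomial pairwise force laws, Weliky-Oster and Nagai-Honda
    vertex forces, derived constitutive pressure laws with their
    diffusion coefficients and stability thresholds, paired micro/macro
    experiment drivers, and ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
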