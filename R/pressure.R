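#' Coarse-grained constitutive pressure laws
#'
#' A `pressure_law` encodes the macroscopic map from cell volume
#' `V = 1/rho` to pressure obtained by coarse-graining a microscopic
#' force model under the regular-shape idealization (factor
#' `xi_d(J)`, see [xi_factor()]).
#'
#' * `pressure_law_cbm()`: from a center-based force `g`,
#'   `p(V) = -(J xi_d/(d mu)) V^(1/d) g(2 xi_d V^(1/d))`, which in 1D
#'   reduces to `p = -(1/mu) V g(V)`.
#' * `pressure_law_wo()`: from the 2D Weliky-Oster vertex force,
#'   `p(V) = (2/(J xi_2 mu)) V^(1/2) (sigma/V - 4 kappa cos(2 pi/J)
#'   V^(1/2)/xi_2)`.
#' * `pressure_law_power()`: the gas-law analogue `p = K rho^gamma`
#'   with `K > 0`, `gamma > 1`.
#'
#' The mobility `mu` is the Darcy coefficient; for a center-based law it
#' is by default the same coefficient that scales the force, so that the
#' two occurrences cancel in the transport equation, as they do in the
#' microscopic model.
#'
#' @param force a `force_law` ([exp_force()] / [poly_force()]).
#' @param d dimension (1, 2 or 3).
#' @param J neighbor count; defaults 2/6/12 for d = 1/2/3.
#' @param mu Darcy mobility.
#' @param params a [wo_params()].
#' @param K,gamma power-law coefficient and exponent.
#' @param xi_override optional d = 3 shape factor override.
#' @return A `pressure_law` object.
#' @examples
#' law <- pressure_law_cbm(exp_force(), d = 1)
#' law_pressure(law, V = c(0.8, 1, 1.2))
#' @name pressure_law
NULL

default_J <- function(d) c(2L, 6L, 12L)[d]

#' @rdname pressure_law
#' @export
pressure_law_cbm <- function(force, d, J = default_J(d),
                             mu = force$mu %||% 1, xi_override = NULL) {
  if (!d %in% 1:3) abort("`d` must be 1, 2 or 3.")
  if (d == 1 && J != 2) abort("in 1D the neighbor count is 2.")
  if (mu <= 0) abort("`mu` must be positive.")
  structure(list(kind = "cbm", d = d, J = J,
                 xi = xi_factor(d, J, xi_override), mu = mu, force = force),
            class = "pressure_law")
}

#' @rdname pressure_law
#' @export
pressure_law_wo <- function(params, J = 6, mu = 1) {
  if (mu <= 0) abort("`mu` must be positive.")
  structure(list(kind = "weliky_oster", d = 2, J = J, xi = xi_factor(2, J),
                 mu = mu, params = params),
            class = "pressure_law")
}

#' @rdname pressure_law
#' @export
pressure_law_power <- function(K, gamma) {
  if (K <= 0 || gamma <= 1) abort("need K > 0 and gamma > 1.")
  structure(list(kind = "power_law", d = NA_integer_, J = NA_integer_,
                 xi = NA_real_, mu = 1, K = K, gamma = gamma),
            class = "pressure_law")
}

#' @export
print.pressure_law <- function(x, ...) {
  cat("<pressure_law:", x$kind, ">")
  if (x$kind != "power_law")
    cat(" d =", x$d, " J =", x$J, " xi =", signif(x$xi, 6), " mu =", x$mu)
  else cat(" K =", x$K, " gamma =", x$gamma)
  cat("\n")
  invisible(x)
}

#' Evaluate a pressure law
#'
#' `law_pressure()` evaluates `p(V)` for any `pressure_law`;
#' `cbm_pressure()`, `wo_pressure()` and `power_law_pressure()` are the
#' explicit forms.  The center-based pressure vanishes wherever the
#' scaled force argument leaves the force support, and is zero exactly at
#' the equilibrium volume `V0 = (s/(2 xi_d))^d`.
#'
#' @param law a `pressure_law`.
#' @param V cell volume(s), positive.
#' @param rho density value(s), positive.
#' @param K,gamma power-law parameters.
#' @return numeric pressure(s).
#' @export
law_pressure <- function(law, V) {
  if (any(V <= 0)) abort("`V` must be positive.")
  switch(law$kind,
    cbm = cbm_pressure(V, law),
    weliky_oster = wo_pressure(V, law),
    power_law = power_law_pressure(1 / V, law$K, law$gamma),
    abort("unknown pressure-law kind."))
}

#' @rdname law_pressure
#' @export
cbm_pressure <- function(V, law) {
  stopifnot(law$kind == "cbm")
  if (any(V <= 0)) abort("`V` must be positive.")
  d <- law$d; xi <- law$xi
  -(law$J * xi / (d * law$mu)) * V^(1 / d) *
    force_g(law$force, 2 * xi * V^(1 / d))
}

#' @rdname law_pressure
#' @export
wo_pressure <- function(V, law) {
  stopifnot(law$kind == "weliky_oster")
  if (any(V <= 0)) abort("`V` must be positive.")
  xi <- law$xi; p <- law$params
  (2 / (law$J * xi * law$mu)) * sqrt(V) *
    (p$sigma / V - 4 * p$kappa * cos(2 * pi / law$J) * sqrt(V) / xi)
}

#' @rdname law_pressure
#' @export
power_law_pressure <- function(rho, K, gamma) {
  if (any(rho <= 0)) abort("`rho` must be positive.")
  if (K <= 0 || gamma <= 1) abort("need K > 0 and gamma > 1.")
  K * rho^gamma
}

#' Discrete interface pressure of the center-based model
#'
#' The exact discrete pressure at the interface between cells i and j,
#' `p_ij = -(V_i/(mu a_ij)) g(r_ij)`, or -- when the geometry is
#' summarized by the regular-shape factors instead of an explicit
#' tessellation -- the shape-closed form
#' `p_ij = -(J xi_d/(d mu)) V_i^(1/d) g(xi_d (V_i^(1/d) + V_j^(1/d)))`.
#' With `V_i = V_j = V` the shape-closed form equals the continuum
#' [cbm_pressure()].
#'
#' @param V_i,V_j cell volumes, positive.
#' @param law a center-based `pressure_law`.
#' @param a_ij,r_ij interface measure and center distance; supply both
#'   for the exact discrete form, omit for the shape-closed form.
#' @return numeric pressure(s).
#' @export
cbm_interface_pressure <- function(V_i, V_j = NULL, law, a_ij = NULL,
                                   r_ij = NULL) {
  stopifnot(law$kind == "cbm")
  if (any(V_i <= 0)) abort("`V_i` must be positive.")
  if (!is.null(a_ij) && !is.null(r_ij)) {
    if (any(a_ij <= 0)) abort("`a_ij` must be positive.")
    return(-(V_i / (law$mu * a_ij)) * force_g(law$force, r_ij))
  }
  if (is.null(V_j)) abort("supply `V_j` (shape-closed form) or `a_ij` and `r_ij`.")
  if (any(V_j <= 0)) abort("`V_j` must be positive.")
  d <- law$d; xi <- law$xi
  -(law$J * xi / (d * law$mu)) * V_i^(1 / d) *
    force_g(law$force, xi * (V_i^(1 / d) + V_j^(1 / d)))
}

#' Discrete 1D Weliky-Oster pressure
#'
#' In 1D the Weliky-Oster force function `f(V) = sigma/V` makes
#' `V f(V)` constant, so no pointwise pressure field exists; the usable
#' discrete pressure at cell j as seen from the updating cell i is
#' `p_j = (1/mu) V_i f(V_j)`, deliberately i-dependent.  It is a flux
#' ingredient of [fvm_step_wo_1d()], not a field.
#'
#' @param V_i updating cell volume.
#' @param V_j evaluated cell volume.
#' @param sigma area force coefficient.
#' @param mu mobility.
#' @return numeric pressure(s).
#' @export
wo_discrete_pressure_1d <- function(V_i, V_j, sigma, mu = 1) {
  if (any(V_i <= 0) || any(V_j <= 0)) abort("volumes must be positive.")
  if (sigma <= 0 || mu <= 0) abort("`sigma` and `mu` must be positive.")
  (1 / mu) * V_i * (sigma / V_j)
}

#' Diffusion-law derivative dp/drho
#'
#' The diffusion coefficient of the transport PDE is
#' `mu rho dp/drho`; this evaluates `dp/drho` analytically for each law.
#' For a center-based law,
#' `dp/drho = (J xi_d/(d^2 mu)) rho^(-(d+1)/d) (g(u) + u g'(u))` with
#' `u = 2 xi_d rho^(-1/d)` and `g'` the one-sided derivative of the
#' active branch (0 beyond the cutoff).  For the Weliky-Oster law,
#' `dp/drho = (2/(J xi_2 mu)) (sigma/(2 sqrt(rho)) +
#' 4 kappa cos(2 pi/J)/(xi_2 rho^2))`, positive for every `rho > 0` when
#' `J >= 4`.  For the power law, `K gamma rho^(gamma-1)`.
#'
#' @param rho density value(s), positive.
#' @param law a `pressure_law`.
#' @return numeric derivative(s).
#' @export
dpdrho <- function(rho, law) {
  if (any(rho <= 0)) abort("`rho` must be positive.")
  switch(law$kind,
    cbm = {
      d <- law$d; xi <- law$xi
      u <- 2 * xi * rho^(-1 / d)
      (law$J * xi / (d^2 * law$mu)) * rho^(-(d + 1) / d) *
        (force_g(law$force, u) + u * force_gprime(law$force, u))
    },
    weliky_oster = {
      p <- law$params
      (2 / (law$J * law$xi * law$mu)) *
        (p$sigma / (2 * sqrt(rho)) +
           4 * p$kappa * cos(2 * pi / law$J) / (law$xi * rho^2))
    },
    power_law = law$K * law$gamma * rho^(law$gamma - 1),
    abort("unknown pressure-law kind."))
}

#' Stability thresholds of a center-based pressure law
#'
#' A center-based force with cutoff `r_A` yields a diffusion coefficient
#' that vanishes at low density (cells out of force range) and is
#' negative -- the transport equation is ill-posed -- in a density band
#' just above that.  Returns the density below which the coefficient is
#' negative (`rho_unstable_below`, the sign change of [dpdrho()] inside
#' the force support, located by bracketing and bisection to 1e-10) and
#' the density below which the force support is left entirely
#' (`rho_vanish_below = (2 xi_d / r_A)^d`).  A second, very-high-density
#' sign change of the 1D exponential law is exposed as the attribute
#' `"rho_high_diagnostic"`.
#'
#' @param law a center-based `pressure_law` whose force has a cutoff.
#' @return tibble with columns `rho_unstable_below`, `rho_vanish_below`
#'   and `always_stable` (TRUE when no sign change exists in the
#'   support, in which case `rho_unstable_below` is `NA`).
#' @examples
#' stability_thresholds(pressure_law_cbm(exp_force(), d = 1))
#' @export
stability_thresholds <- function(law) {
  stopifnot(law$kind == "cbm")
  g <- law$force
  d <- law$d; xi <- law$xi
  rho_vanish <- (2 * xi / g$r_A)^d
  rho_eq <- (2 * xi / g$s)^d      # equilibrium density, where dpdrho > 0
  h <- function(rho) dpdrho(rho, law)
  eps <- 1e-9
  lo <- rho_vanish * (1 + eps)
  hi <- rho_eq
  root <- NA_real_
  if (is.finite(hi) && h(lo) * h(hi) < 0) {
    root <- uniroot(h, c(lo, hi), tol = 1e-10)$root
  } else {
    # scan the support for a bracket
    grid <- exp(seq(log(lo), log(hi), length.out = 256))
    sgn <- sign(h(grid))
    flip <- which(diff(sgn) != 0)
    if (length(flip))
      root <- uniroot(h, grid[c(max(flip), max(flip) + 1)], tol = 1e-10)$root
  }
  out <- tibble(
    rho_unstable_below = root,
    rho_vanish_below = rho_vanish,
    always_stable = is.na(root))
  # high-density companion root (above equilibrium), diagnostic only
  hi2 <- tryCatch({
    grid <- exp(seq(log(rho_eq), log(rho_eq * 1e3), length.out = 512))
    sgn <- sign(h(grid))
    flip <- which(diff(sgn) != 0)
    if (length(flip))
      uniroot(h, grid[c(flip[1], flip[1] + 1)], tol = 1e-10)$root
    else NA_real_
  }, error = function(e) NA_real_)
  attr(out, "rho_high_diagnostic") <- hi2
  out
}

#' Tabulate a pressure law
#'
#' Evaluates pressure and diffusion derivative on a volume grid, for
#' plotting constitutive curves.
#'
#' @param law a `pressure_law`.
#' @param vmin,vmax volume range, positive.
#' @param n number of points.
#' @return tibble with columns `V`, `rho`, `p`, `dpdrho`.
#' @export
pressure_table <- function(law, vmin, vmax, n = 200) {
  if (vmin <= 0 || vmax <= vmin) abort("need 0 < vmin < vmax.")
  V <- seq(vmin, vmax, length.out = n)
  tibble(V = V, rho = 1 / V, p = law_pressure(law, V),
         dpdrho = dpdrho(1 / V, law))
}

#' @export
glance.pressure_law <- function(x, ...) {
  if (x$kind == "cbm") {
    th <- stability_thresholds(x)
    tibble(kind = x$kind, d = x$d, J = x$J, xi = x$xi, mu = x$mu,
           rho_unstable_below = th$rho_unstable_below,
           rho_vanish_below = th$rho_vanish_below)
  } else {
    tibble(kind = x$kind, d = x$d, J = x$J, xi = x$xi, mu = x$mu,
           rho_unstable_below = NA_real_, rho_vanish_below = NA_real_)
  }
}
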