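#' Exponential center-based force law
#'
#' Pairwise force magnitude between two cell centers at distance `r`:
#' `g(r) = mu (r - s) exp(-c (r - s))` for `r<=r_A` and 0 beyond the
#' cutoff, so centers repel when overlapping (`r<s`), adhere for
#' `s < r < r_A`, and ignore each other beyond `r_A`.  The discontinuity
#' at `r_A` is part of the model and is kept as is.  Defaults are the
#' reference parameter set used throughout the package's experiments.
#'
#' @param mu force strength (velocity per length).
#' @param s rest distance where the force vanishes (length).
#' @param c adhesion decay rate (1/length).
#' @param r_A cutoff distance (length), `r_A > s`.
#' @param eta viscosity scaling (dimensionless, default 1).
#' @return A `force_law` object of subclass `exp_force`.
#' @examples
#' g <- exp_force()
#' force_g(g, c(1, 1.2, 1.6))   # 0 at rest, adhesive, 0 past cutoff
#' @export
exp_force <- function(mu = 50, s = 1, c = 10, r_A = 1.5, eta = 1) {
  if (s <= 0 || c <= 0 || mu <= 0 || eta <= 0 || r_A <= s)
    abort("need mu > 0, s > 0, c > 0, eta > 0 and r_A > s.")
  structure(list(kind = "exp", mu = mu, s = s, c = c, r_A = r_A, eta = eta),
            class = c("exp_force", "force_law"))
}

#' Polynomial center-based force law
#'
#' The piecewise-polynomial repulsion/adhesion force
#' `g(r) = -c_r (1 - r/r_R)^(n+1) + c_a (1 - r/r_A)^(n+1)` for
#' `r<=r_R`, the adhesion branch alone for `r_R<r<=r_A`, and 0
#' beyond `r_A`; continuous everywhere.  With `c_a < c_r` it has a single
#' interior zero `s < r_R` given by [poly_zero_distance()].
#'
#' @param c_r repulsion coefficient; `c_r > c_a`.
#' @param c_a adhesion coefficient, non-negative.
#' @param r_R repulsion range; `0 < r_R < r_A`.
#' @param r_A adhesion cutoff.
#' @param n non-negative integer exponent.
#' @param eta viscosity scaling.
#' @return A `force_law` object of subclass `poly_force`.
#' @export
poly_force <- function(c_r, c_a, r_R, r_A, n = 1, eta = 1) {
  if (c_a >= c_r) abort("`c_a` must be smaller than `c_r`.")
  if (c_a < 0) abort("`c_a` must be non-negative.")
  if (!(r_R > 0 && r_A > r_R)) abort("need 0 < r_R < r_A.")
  if (n < 0 || n != round(n)) abort("`n` must be a non-negative integer.")
  if (eta <= 0) abort("`eta` must be positive.")
  law <- structure(
    list(kind = "poly", c_r = c_r, c_a = c_a, r_R = r_R, r_A = r_A,
         n = as.integer(n), eta = eta),
    class = c("poly_force", "force_law"))
  s <- poly_zero_distance(law)
  if (!(s > 0 && s <= r_R)) abort("derived zero distance not in (0, r_R].")
  law$s <- s
  law
}

#' @export
print.force_law <- function(x, ...) {
  cat("<force_law:", x$kind, "> ",
      paste(names(x)[-1], unlist(x[-1]), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a force law and its derivative
#'
#' `force_g()` evaluates the signed force magnitude `g(r)`;
#' `force_gprime()` evaluates the analytic derivative of the active
#' branch (0 beyond the cutoff; at the exponential cutoff discontinuity
#' the one-sided derivative from below is used).
#'
#' @param law a `force_law` from [exp_force()] or [poly_force()].
#' @param r distance(s), non-negative.
#' @return numeric vector.
#' @export
force_g <- function(law, r) {
  r <- as.numeric(r)
  if (any(r < 0)) abort("`r` must be non-negative.")
  UseMethod("force_g")
}

#' @export
force_g.exp_force <- function(law, r) {
  ifelse(r <= law$r_A,
         law$mu * (r - law$s) * exp(-law$c * (r - law$s)), 0)
}

#' @export
force_g.poly_force <- function(law, r) {
  np1 <- law$n + 1
  rep_ <- -law$c_r * pmax(1 - r / law$r_R, 0)^np1
  adh <- law$c_a * (1 - r / law$r_A)^np1
  ifelse(r > law$r_A, 0, ifelse(r > law$r_R, adh, rep_ + adh))
}

#' @rdname force_g
#' @export
force_gprime <- function(law, r) {
  r <- as.numeric(r)
  if (any(r < 0)) abort("`r` must be non-negative.")
  UseMethod("force_gprime")
}

#' @export
force_gprime.exp_force <- function(law, r) {
  ifelse(r <= law$r_A,
         law$mu * exp(-law$c * (r - law$s)) * (1 - law$c * (r - law$s)), 0)
}

#' @export
force_gprime.poly_force <- function(law, r) {
  np1 <- law$n + 1
  drep <- np1 * law$c_r / law$r_R * pmax(1 - r / law$r_R, 0)^law$n
  dadh <- -np1 * law$c_a / law$r_A * (1 - r / law$r_A)^law$n
  ifelse(r > law$r_A, 0, ifelse(r > law$r_R, dadh, drep + dadh))
}

#' Rest distance of the polynomial force law
#'
#' The interior zero `s` of the polynomial force,
#' `s = r_A r_R (c_r^(1/(n+1)) - c_a^(1/(n+1))) /
#' (c_r^(1/(n+1)) r_A - c_a^(1/(n+1)) r_R)`, which satisfies `s < r_R`.
#'
#' @param law a `poly_force` (or a parameter list with the same fields).
#' @return the rest distance (length).
#' @export
poly_zero_distance <- function(law) {
  if (law$c_a >= law$c_r) abort("`c_a` must be smaller than `c_r`.")
  e <- 1 / (law$n + 1)
  cr <- law$c_r^e; ca <- law$c_a^e
  law$r_A * law$r_R * (cr - ca) / (cr * law$r_A - ca * law$r_R)
}

#' Rest distance of any force law
#' @noRd
force_rest <- function(law) law$s

#' Center-based model velocities
#'
#' Overdamped velocities of all cell centers,
#' `v_i = (1/eta) sum_j rhat_ij g(r_ij)`, where the sum runs over every
#' other center within the cutoff `r_A` (found by a spatial bucket-grid
#' query, not restricted to Voronoi neighbors).  Frozen boundary cells
#' still receive their computed velocity; the integrator zeroes it.
#'
#' @param centers data frame with coordinate columns `x[, y]`.
#' @param law a `force_law`.
#' @return tibble with columns `cell` and `vx[, vy]`.
#' @examples
#' cbm_velocities(data.frame(x = c(0, 1.2, 2.3)), exp_force())
#' @export
cbm_velocities <- function(centers, law) {
  m <- coord_matrix(centers)
  d <- ncol(m)
  n <- nrow(m)
  if (d == 1) {
    pr <- cg_pairs_within(m[, 1], rep(0, n), law$r_A)
  } else {
    pr <- cg_pairs_within(m[, 1], m[, 2], law$r_A)
  }
  v <- matrix(0, n, d)
  if (length(pr$i)) {
    scale <- max(apply(m, 2, function(z) diff(range(z))), 1)
    if (any(pr$r < 1e-12 * scale)) {
      k <- which(pr$r < 1e-12 * scale)[1]
      abort(sprintf("coincident cell centers %d and %d.", pr$i[k], pr$j[k]))
    }
    gv <- force_g(law, pr$r) / law$eta
    for (k in seq_len(d)) {
      comp <- (m[pr$j, k] - m[pr$i, k]) / pr$r * gv
      acc <- rowsum(c(comp, -comp), c(pr$i, pr$j))
      v[as.integer(rownames(acc)), k] <- acc[, 1]
    }
  }
  out <- tibble(cell = seq_len(n), vx = v[, 1])
  if (d == 2) out$vy <- v[, 2]
  out
}
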