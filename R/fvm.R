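#' Cartesian finite-volume grid
#'
#' Builds an equidistant (1D) or Cartesian (2D) grid of cell-centered
#' elements on a rectangular domain.  Element volumes are
#' `omega = prod(dx)`, interface measures `sigma = dx^(d-1)` per axis,
#' and center distances equal the spacing.  If the requested spacing does
#' not divide an extent to within 1e-9 (relative), the spacing on that
#' axis is adjusted to the nearest exact divisor and the adjustment is
#' recorded in the grid's `$notes`.
#'
#' @param domain a [sim_domain()] with `d` 1 or 2.
#' @param spacing numeric scalar or per-axis vector of element sizes.
#' @return An `fvm_grid`: `$d`, `$n` (elements per axis), `$dx`,
#'   `$omega`, `$centers` tibble, `$domain`, `$notes`.
#' @examples
#' build_grid(sim_domain(0, 1), 0.25)
#' @export
build_grid <- function(domain, spacing) {
  if (!domain$d %in% 1:2) abort("grids support d = 1 or 2.")
  spacing <- rep_len(as.numeric(spacing), domain$d)
  if (any(spacing <= 0)) abort("`spacing` must be positive.")
  ext <- domain$upper - domain$lower
  n <- numeric(domain$d); dx <- numeric(domain$d); notes <- character()
  for (k in seq_len(domain$d)) {
    nk <- ext[k] / spacing[k]
    if (abs(nk - round(nk)) > 1e-9 * max(nk, 1)) {
      nk <- max(round(nk), 1)
      notes <- c(notes, sprintf(
        "axis %d: spacing %g adjusted to %g to divide extent %g exactly",
        k, spacing[k], ext[k] / nk, ext[k]))
      warn(notes[length(notes)])
    } else nk <- round(nk)
    n[k] <- nk
    dx[k] <- ext[k] / nk
  }
  cx <- domain$lower[1] + (seq_len(n[1]) - 0.5) * dx[1]
  centers <- if (domain$d == 1) tibble(i = seq_len(n[1]), x = cx)
  else {
    cy <- domain$lower[2] + (seq_len(n[2]) - 0.5) * dx[2]
    g <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]))
    tibble(i = g$i, j = g$j, x = cx[g$i], y = cy[g$j])
  }
  structure(list(d = domain$d, n = as.integer(n), dx = dx,
                 omega = prod(dx), centers = centers, domain = domain,
                 notes = notes),
            class = "fvm_grid")
}

#' @export
print.fvm_grid <- function(x, ...) {
  cat("<fvm_grid> d =", x$d, ":", paste(x$n, collapse = " x "),
      "elements, dx =", paste(signif(x$dx, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Density field on a finite-volume grid
#'
#' @param grid an [build_grid()] grid.
#' @param rho non-negative density values, one per element, ordered as
#'   `grid$centers` (x index fastest in 2D).
#' @param t field time.
#' @return A `grid_field` object.
#' @export
grid_field <- function(grid, rho, t = 0) {
  rho <- as.numeric(rho)
  if (length(rho) != prod(grid$n)) abort("`rho` has the wrong length.")
  if (any(rho < 0)) abort("`rho` must be non-negative.")
  structure(list(grid = grid, rho = rho, t = t), class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat("<grid_field> t =", x$t, ", mass =", total_mass(x),
      ", rho in [", signif(min(x$rho), 4), ",", signif(max(x$rho), 4), "]\n")
  invisible(x)
}

#' @rdname grid_field
#' @param x a `grid_field`.
#' @param ... unused.
#' @export
tidy.grid_field <- function(x, ...) {
  out <- x$grid$centers
  out$rho <- x$rho
  out$t <- x$t
  out
}

#' Total mass of a density field
#'
#' `sum_i omega_i rho_i`; exactly conserved by [fvm_step()] under the
#' zero-flux (Neumann) boundary condition.
#'
#' @param field a `grid_field`.
#' @return numeric scalar.
#' @export
total_mass <- function(field) field$grid$omega * sum(field$rho)

# element pressures with the p(0) = 0 convention for empty elements
element_pressure <- function(law, rho) {
  p <- numeric(length(rho))
  pos <- rho > 0
  p[pos] <- law_pressure(law, 1 / rho[pos])
  p
}

#' One forward-Euler finite-volume step of the density transport equation
#'
#' Advances `drho/dt = mu div(rho grad p)` by one explicit step:
#' `rho_i <- rho_i + (mu dt/omega) sum_j (rho_i+rho_j)/2 (p_j-p_i)/l_ij
#' sigma_ij`, with element pressures `p_i = p(1/rho_i)` (0 for empty
#' elements) and zero-flux boundary faces.  Fluxes telescope, so total
#' mass is conserved to round-off.  A step that produces a negative
#' density is rejected -- in the unstable density band of a center-based
#' law this signals too large a `dt`.
#'
#' @param field a `grid_field`.
#' @param law a `pressure_law`.
#' @param dt timestep.
#' @param mu Darcy mobility; defaults to the law's `mu` so that the two
#'   occurrences cancel as in the microscopic model.
#' @return the advanced `grid_field`.
#' @export
fvm_step <- function(field, law, dt, mu = law$mu) {
  if (dt <= 0) abort("`dt` must be positive.")
  p <- element_pressure(law, field$rho)
  fvm_apply(field, p, dt * mu, dt)
}

# shared flux kernel: rho += (c/omega) * div of 0.5(rho_i+rho_j)(q_j-q_i)/l * sigma
fvm_apply <- function(field, q, c_, dt) {
  g <- field$grid
  rho <- field$rho
  if (g$d == 1) {
    dxx <- g$dx[1]
    f <- 0.5 * (rho[-length(rho)] + rho[-1]) * diff(q) / dxx # * sigma = 1
    upd <- c_ / g$omega * (c(f, 0) - c(0, f))
    new <- rho + upd
  } else {
    nx <- g$n[1]; ny <- g$n[2]
    R <- matrix(rho, nx, ny)
    Q <- matrix(q, nx, ny)
    fx <- 0.5 * (R[-nx, , drop = FALSE] + R[-1, , drop = FALSE]) *
      (Q[-1, , drop = FALSE] - Q[-nx, , drop = FALSE]) / g$dx[1] * g$dx[2]
    fy <- 0.5 * (R[, -ny, drop = FALSE] + R[, -1, drop = FALSE]) *
      (Q[, -1, drop = FALSE] - Q[, -ny, drop = FALSE]) / g$dx[2] * g$dx[1]
    zx <- matrix(0, 1, ny); zy <- matrix(0, nx, 1)
    upd <- c_ / g$omega *
      ((rbind(fx, zx) - rbind(zx, fx)) + (cbind(fy, zy) - cbind(zy, fy)))
    new <- rho + as.numeric(upd)
  }
  if (any(new < 0)) {
    k <- which(new < 0)[1]
    abort(sprintf("negative density at element %d after step; use a smaller dt.", k))
  }
  field$rho <- new
  field$t <- field$t + dt
  field
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specialized 1D schemes
#'
#' `fvm_step_cbm_1d()` advances a 1D field with the center-based force
#' directly: `rho_i <- rho_i - (dt/dx^2) sum_j rho_ij (V_j g(V_j) -
#' V_i g(V_i))` with `V = 1/rho` and `rho_ij = (rho_i+rho_j)/2`.  It is
#' algebraically identical to [fvm_step()] with the 1D center-based
#' pressure law (the force scale and the Darcy mobility cancel).
#'
#' `fvm_step_wo_1d()` advances a 1D field with the Weliky-Oster force
#' function `f(V) = sigma/V` using the i-dependent discrete pressure
#' `p_j = V_i f(V_j)/mu`:
#' `rho_i <- rho_i + (dt/dx^2) (rho_ij V_i (f(V_j)-f(V_i)) +
#' rho_ki V_i (f(V_k)-f(V_i)))`, zero-flux at the boundary.  Because of
#' the `V_i` factor this scheme is not in conservative flux form; its
#' mass defect per step is of second order in the density differences.
#'
#' @param field a 1D `grid_field`.
#' @param force a `force_law`.
#' @param sigma Weliky-Oster area force coefficient.
#' @param dt timestep.
#' @param mu mobility of the discrete Weliky-Oster pressure.
#' @return the advanced `grid_field`.
#' @export
fvm_step_cbm_1d <- function(field, force, dt) {
  if (field$grid$d != 1) abort("1D grid required.")
  if (dt <= 0) abort("`dt` must be positive.")
  rho <- field$rho
  W <- numeric(length(rho))
  pos <- rho > 0
  V <- 1 / rho[pos]
  W[pos] <- V * force_g(force, V)
  dxx <- field$grid$dx[1]
  f <- 0.5 * (rho[-length(rho)] + rho[-1]) * diff(W)
  new <- rho - dt / dxx^2 * (c(f, 0) - c(0, f))
  if (any(new < 0)) {
    k <- which(new < 0)[1]
    abort(sprintf("negative density at element %d after step; use a smaller dt.", k))
  }
  field$rho <- new
  field$t <- field$t + dt
  field
}

#' @rdname fvm_step_cbm_1d
#' @export
fvm_step_wo_1d <- function(field, sigma, dt, mu = 1) {
  if (field$grid$d != 1) abort("1D grid required.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (dt <= 0) abort("`dt` must be positive.")
  rho <- field$rho
  n <- length(rho)
  fV <- sigma * rho                       # f(V) = sigma/V = sigma rho
  dxx <- field$grid$dx[1]
  Vi <- ifelse(rho > 0, 1 / rho, 0)
  rr <- c(rho[-1], 0); rl <- c(0, rho[-n])          # neighbor densities
  fr <- c(fV[-1], 0); fl <- c(0, fV[-n])
  right <- c(rep(1, n - 1), 0); left <- c(0, rep(1, n - 1))
  upd <- (0.5 * (rho + rr) * Vi * (fr - fV) * right +
            0.5 * (rho + rl) * Vi * (fl - fV) * left) / mu
  new <- rho + dt / dxx^2 * upd
  if (any(new < 0)) {
    k <- which(new < 0)[1]
    abort(sprintf("negative density at element %d after step; use a smaller dt.", k))
  }
  field$rho <- new
  field$t <- field$t + dt
  field
}

#' Run a macroscopic finite-volume simulation
#'
#' Repeated explicit stepping to time `T` with density snapshots and a
#' run manifest that records the relative mass drift and a conservative
#' (not enforced) timestep estimate
#' `dt <= omega_min l_min / (mu max|rho dp/drho| sum sigma)`.
#'
#' @param field initial `grid_field`.
#' @param law a `pressure_law` (ignored for `scheme = "wo_1d"`).
#' @param dt timestep.
#' @param T final time; steps `= round(T/dt)`.
#' @param save_every snapshot stride in steps (default: first and last).
#' @param scheme `"pressure"` (generic [fvm_step()]), `"cbm_1d"` or
#'   `"wo_1d"`.
#' @param sigma,mu parameters of the `"wo_1d"` scheme.
#' @return A `macro_trajectory`: `$frames`, `$times`, `$final`,
#'   `$manifest` (with `mass0`, `mass_drift`, `dt_stable_estimate`).
#' @export
run_macro <- function(field, law = NULL, dt, T, save_every = NULL,
                      scheme = c("pressure", "cbm_1d", "wo_1d"),
                      sigma = NULL, mu = NULL) {
  scheme <- match.arg(scheme)
  if (dt <= 0) abort("`dt` must be positive.")
  if (T < 0) abort("`T` must be non-negative.")
  n_steps <- round(T / dt)
  if (is.null(save_every)) save_every <- max(n_steps, 1)
  stepper <- switch(scheme,
    pressure = function(f) fvm_step(f, law, dt),
    cbm_1d = function(f) fvm_step_cbm_1d(f, law$force, dt),
    wo_1d = function(f) fvm_step_wo_1d(f, sigma, dt, mu %||% 1))
  mass0 <- total_mass(field)
  dt_est <- NA_real_
  if (scheme == "pressure" && any(field$rho > 0)) {
    g <- field$grid
    rp <- field$rho[field$rho > 0]
    dmax <- max(abs(rp * dpdrho(rp, law))) * law$mu
    sig_sum <- if (g$d == 1) 2 else 2 * (g$dx[1] + g$dx[2])
    if (dmax > 0)
      dt_est <- g$omega * min(g$dx) / (dmax * sig_sum)
  }
  frames <- list(field)
  times <- field$t
  for (n in seq_len(n_steps)) {
    field <- tryCatch(stepper(field), error = function(e)
      abort(sprintf("step %d failed: %s", n, conditionMessage(e))))
    if (n %% save_every == 0 || n == n_steps) {
      frames[[length(frames) + 1]] <- field
      times <- c(times, field$t)
    }
  }
  drift <- abs(total_mass(field) - mass0) / max(abs(mass0), 1e-300)
  structure(
    list(frames = frames, times = times, final = field,
         manifest = list(scheme = scheme, dt = dt, T = T, n_steps = n_steps,
                         mass0 = mass0, mass_drift = drift,
                         dt_stable_estimate = dt_est)),
    class = "macro_trajectory")
}

#' @export
print.macro_trajectory <- function(x, ...) {
  cat("<macro_trajectory:", x$manifest$scheme, ">", x$manifest$n_steps,
      "steps to t =", max(x$times),
      "; relative mass drift", signif(x$manifest$mass_drift, 3), "\n")
  invisible(x)
}

#' @rdname run_macro
#' @param x a `macro_trajectory`.
#' @param ... unused.
#' @export
tidy.macro_trajectory <- function(x, ...) {
  dplyr::bind_rows(lapply(x$frames, tidy))
}

#' @rdname run_macro
#' @export
glance.macro_trajectory <- function(x, ...) {
  tibble(scheme = x$manifest$scheme, n_steps = x$manifest$n_steps,
         t_final = max(x$times), mass0 = x$manifest$mass0,
         mass_drift = x$manifest$mass_drift,
         dt = x$manifest$dt, dt_stable_estimate = x$manifest$dt_stable_estimate)
}
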