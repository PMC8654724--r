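#' Microscopic simulation state
#'
#' `micro_state_cbm()` wraps a set of cell centers for center-based
#' integration; `micro_state_vbm()` wraps a vertex mesh for vertex-based
#' integration.  Cells whose Voronoi region touches the domain boundary
#' (CBM) and boundary vertices (VBM) are frozen by default, which keeps
#' the total mass in the domain constant.
#'
#' @param centers data frame with `x[, y]` columns.
#' @param domain a [sim_domain()].
#' @param frozen optional logical vector overriding the default frozen
#'   mask.
#' @param mesh a `vertex_mesh` (see [build_vertex_mesh()]).
#' @return A `micro_state` object with fields `kind` ("cbm" or "vbm"),
#'   `t`, and the model state.
#' @export
micro_state_cbm <- function(centers, domain, frozen = NULL) {
  m <- coord_matrix(centers, domain$d)
  tess <- retessellate(m, domain)
  if (is.null(frozen)) frozen <- tess$cells$boundary
  if (length(frozen) != nrow(m)) abort("`frozen` has the wrong length.")
  structure(list(kind = "cbm", d = domain$d, domain = domain, coords = m,
                 frozen = frozen, t = 0, tess = tess, tess_t = 0),
            class = "micro_state")
}

#' @rdname micro_state_cbm
#' @export
micro_state_vbm <- function(mesh, frozen = NULL) {
  if (mesh$degenerate)
    abort("degenerate vertex mesh; the vertex model needs 3 cells per interior vertex.")
  if (is.null(frozen)) frozen <- mesh$vertices$boundary
  stats <- mesh_cell_stats(mesh)
  el <- mesh_edge_lengths(mesh)
  structure(list(kind = "vbm", d = 2L, domain = mesh$domain, mesh = mesh,
                 frozen = frozen, t = 0, stats = stats,
                 edge0 = mean(el)),
            class = "micro_state")
}

#' @export
print.micro_state <- function(x, ...) {
  n <- if (x$kind == "cbm") nrow(x$coords) else length(x$mesh$cells)
  cat("<micro_state:", x$kind, "> ", n, "cells, t =", x$t, "\n")
  invisible(x)
}

retessellate <- function(m, domain, mesh = FALSE, polygons = FALSE) {
  df <- as.data.frame(m)
  names(df) <- c("x", "y", "z")[seq_len(ncol(m))]
  if (domain$d == 1) tessellate_1d(df, domain)
  else tessellate_2d(df, domain, mesh = mesh, polygons = polygons)
}

mesh_edge_lengths <- function(mesh) {
  e1 <- unlist(lapply(mesh$cells, function(r) r))
  e2 <- unlist(lapply(mesh$cells, function(r) c(r[-1], r[1])))
  keep <- !duplicated(paste(pmin(e1, e2), pmax(e1, e2)))
  sqrt((mesh$vertices$x[e1[keep]] - mesh$vertices$x[e2[keep]])^2 +
         (mesh$vertices$y[e1[keep]] - mesh$vertices$y[e2[keep]])^2)
}

#' One forward-Euler step of the center-based model
#'
#' Advances non-frozen cell centers by `dt` times their overdamped
#' velocity.  Rejects steps that make centers coincide or, in 1D,
#' reorder -- both signal that `dt` is too large for the force stiffness.
#' The tessellation snapshot is marked stale; [run_micro()] refreshes it
#' at the configured cadence.
#'
#' @param state a CBM `micro_state`.
#' @param law a `force_law`.
#' @param dt timestep, `>= 0`.
#' @return the advanced `micro_state`.
#' @export
step_cbm <- function(state, law, dt) {
  stopifnot(state$kind == "cbm")
  if (dt < 0) abort("`dt` must be non-negative.")
  if (dt == 0) return(state)
  v <- cbm_velocity_matrix(state$coords, law)
  m <- state$coords
  m[!state$frozen, ] <- m[!state$frozen, , drop = FALSE] +
    dt * v[!state$frozen, , drop = FALSE]
  check_step_sanity(m, state)
  state$coords <- m
  state$t <- state$t + dt
  state
}

check_step_sanity <- function(m, state) {
  scale <- max(state$domain$upper - state$domain$lower)
  if (state$d == 1) {
    x <- m[, 1]
    ord <- order(x)
    if (any(diff(x[ord]) < 1e-12 * scale) ||
        !identical(ord, order(state$coords[, 1])))
      abort("step made 1D centers coincide or reorder; use a smaller dt.")
  } else {
    pr <- cg_pairs_within(m[, 1], m[, 2], 1e-9 * scale)
    if (length(pr$i))
      abort(sprintf("step made centers %d and %d coincide; use a smaller dt.",
                    pr$i[1], pr$j[1]))
  }
  invisible(TRUE)
}

# matrix-in matrix-out CBM velocity (hot path; cbm_velocities() wraps it)
cbm_velocity_matrix <- function(m, law) {
  d <- ncol(m); n <- nrow(m)
  pr <- if (d == 1) cg_pairs_within(m[, 1], rep(0, n), law$r_A)
        else cg_pairs_within(m[, 1], m[, 2], law$r_A)
  v <- matrix(0, n, d)
  if (length(pr$i)) {
    if (any(pr$r == 0)) {
      k <- which(pr$r == 0)[1]
      abort(sprintf("coincident cell centers %d and %d.", pr$i[k], pr$j[k]))
    }
    gv <- force_g(law, pr$r) / law$eta
    idx <- c(pr$i, pr$j)
    for (k in seq_len(d)) {
      comp <- (m[pr$j, k] - m[pr$i, k]) / pr$r * gv
      acc <- rowsum(c(comp, -comp), idx)
      v[as.integer(rownames(acc)), k] <- acc[, 1]
    }
  }
  v
}

#' One forward-Euler step of the 2D vertex-based model
#'
#' Advances non-frozen interior vertices by `dt` times the
#' Weliky-Oster or Nagai-Honda vertex velocity.  The polygon mesh itself
#' is the state: cell areas and perimeters are recomputed from the moved
#' polygons, with no re-tessellation and no topological (T1/T2) moves;
#' an imminent edge collapse (edge shorter than 1e-6 of the initial mean
#' edge), a non-positive area or a self-intersecting polygon rejects the
#' step.
#'
#' @param state a VBM `micro_state`.
#' @param params [wo_params()] or [nh_params()].
#' @param dt timestep, `>= 0`.
#' @return the advanced `micro_state`.
#' @export
step_vbm <- function(state, params, dt) {
  stopifnot(state$kind == "vbm")
  if (dt < 0) abort("`dt` must be non-negative.")
  if (dt == 0) return(state)
  mesh <- state$mesh
  stats <- state$stats
  vel_fun <- if (inherits(params, "wo_params")) wo_vertex_velocity
             else nh_vertex_velocity
  movers <- which(!state$frozen & !mesh$vertices$boundary)
  # evaluate every velocity on the current mesh before moving anything
  vel <- vapply(movers, function(a) vel_fun(mesh, a, params, stats),
                numeric(2))
  mesh$vertices$x[movers] <- mesh$vertices$x[movers] + dt * vel[1, ]
  mesh$vertices$y[movers] <- mesh$vertices$y[movers] + dt * vel[2, ]
  new_stats <- mesh_cell_stats(mesh)
  if (any(new_stats$V <= 0))
    abort("step produced a non-positive cell area; use a smaller dt.")
  el <- mesh_edge_lengths(mesh)
  if (any(el < 1e-6 * state$edge0))
    abort("step drove an edge near collapse; topological moves are not modelled. Use a smaller dt.")
  bad <- which(vapply(mesh$cells, function(r)
    polygon_self_intersects(mesh$vertices$x[r], mesh$vertices$y[r]),
    logical(1)))
  if (length(bad))
    abort(sprintf("step self-intersected polygon of cell %d; use a smaller dt.", bad[1]))
  state$mesh <- mesh
  state$stats <- new_stats
  state$t <- state$t + dt
  state
}

# any two non-adjacent edges of the ring properly intersect?
polygon_self_intersects <- function(x, y) {
  k <- length(x)
  if (k < 4) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (e in seq_len(k - 2)) {
    for (f in seq((e + 2), k)) {
      if (e == 1 && f == k) next
      d1 <- cross(x[e], y[e], x2[e], y2[e], x[f], y[f])
      d2 <- cross(x[e], y[e], x2[e], y2[e], x2[f], y2[f])
      d3 <- cross(x[f], y[f], x2[f], y2[f], x[e], y[e])
      d4 <- cross(x[f], y[f], x2[f], y2[f], x2[e], y2[e])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Per-cell density of a microscopic state
#'
#' Refreshes the tessellation if it is stale and returns the per-cell
#' density samples `rho_i = 1/V_i` attributed to the cell centers (CBM)
#' or the polygon areas (VBM, centroids).
#'
#' @param state a `micro_state`.
#' @return tibble with center coordinates, `V` and `rho`.
#' @export
density_field <- function(state) {
  if (state$kind == "cbm") {
    if (is.null(state$tess) || state$tess_t != state$t)
      state$tess <- retessellate(state$coords, state$domain)
    cell_density(state$tess)
  } else {
    stats <- mesh_cell_stats(state$mesh)
    ctr <- t(vapply(state$mesh$cells, function(r)
      c(mean(state$mesh$vertices$x[r]), mean(state$mesh$vertices$y[r])),
      numeric(2)))
    tibble(cell = stats$cell, x = ctr[, 1], y = ctr[, 2],
           V = stats$V, rho = 1 / stats$V)
  }
}

#' Geometric-conservation-law volume update
#'
#' Diagnostic alternative to re-tessellation: updates each cell volume by
#' the net flux of the interface velocities through its Voronoi faces,
#' `V_i <- V_i + dt * sum_j n_ij . v_ij a_ij`, with the interface
#' velocity taken as the mean of the two adjacent cell velocities.  With
#' frozen boundary cells the volume increments telescope to zero.
#'
#' @param state a CBM `micro_state` with a current tessellation.
#' @param law a `force_law` (defines the cell velocities).
#' @param dt timestep.
#' @return numeric vector of updated volumes.
#' @export
gcl_volume_update <- function(state, law, dt) {
  stopifnot(state$kind == "cbm")
  if (is.null(state$tess)) abort("state has no tessellation.")
  tess <- if (state$tess_t != state$t)
    retessellate(state$coords, state$domain) else state$tess
  v <- cbm_velocity_matrix(state$coords, law)
  v[state$frozen, ] <- 0
  nb <- tess$neighbors
  vij <- (v[nb$i, , drop = FALSE] + v[nb$j, , drop = FALSE]) / 2
  nrm <- if (state$d == 1) cbind(nb$nx) else cbind(nb$nx, nb$ny)
  flux <- rowSums(nrm * vij) * nb$a_ij
  inc <- rowsum(flux, nb$i)
  V <- tess$cells$V
  V[as.integer(rownames(inc))] <- V[as.integer(rownames(inc))] + dt * inc[, 1]
  V
}

#' Run a microscopic simulation
#'
#' Forward-Euler integration of a CBM or VBM state to time `T`, with
#' frozen boundary cells/vertices, periodic tessellation refreshes (CBM)
#' and density snapshots at a fixed stride.  Deterministic: identical
#' inputs give identical trajectories.
#'
#' @param state a `micro_state`.
#' @param force a `force_law` (CBM) or [wo_params()] / [nh_params()]
#'   (VBM).
#' @param dt timestep.
#' @param T final time (`T >= 0`); the number of steps is
#'   `round(T/dt)`.
#' @param save_every save a density frame every this many steps (default:
#'   only the first and last).
#' @param retessellate_every CBM only: steps between tessellation
#'   refreshes.
#' @return A `micro_trajectory`: `$frames` (list of density tibbles),
#'   `$times`, `$final` (the final `micro_state`), `$manifest`.
#' @export
run_micro <- function(state, force, dt, T, save_every = NULL,
                      retessellate_every = 1) {
  if (dt <= 0) abort("`dt` must be positive.")
  if (T < 0) abort("`T` must be non-negative.")
  if (retessellate_every < 1) abort("`retessellate_every` must be >= 1.")
  n_steps <- round(T / dt)
  if (is.null(save_every)) save_every <- max(n_steps, 1)
  frames <- list(density_field(state))
  times <- state$t
  stepper <- if (state$kind == "cbm") {
    function(s) step_cbm(s, force, dt)
  } else {
    function(s) step_vbm(s, force, dt)
  }
  for (n in seq_len(n_steps)) {
    state <- tryCatch(stepper(state), error = function(e)
      abort(sprintf("step %d failed: %s", n, conditionMessage(e))))
    if (state$kind == "cbm" && (n %% retessellate_every == 0)) {
      state$tess <- retessellate(state$coords, state$domain)
      state$tess_t <- state$t
    }
    if (n %% save_every == 0 || n == n_steps) {
      frames[[length(frames) + 1]] <- density_field(state)
      times <- c(times, state$t)
    }
  }
  structure(
    list(frames = frames, times = times, final = state,
         manifest = list(kind = state$kind, dt = dt, T = T,
                         n_steps = n_steps, save_every = save_every,
                         retessellate_every = retessellate_every)),
    class = "micro_trajectory")
}

#' @export
print.micro_trajectory <- function(x, ...) {
  cat("<micro_trajectory:", x$manifest$kind, ">", x$manifest$n_steps,
      "steps to t =", max(x$times), "with", length(x$frames), "frames\n")
  invisible(x)
}

#' @rdname run_micro
#' @param x a `micro_trajectory`.
#' @param ... unused.
#' @export
tidy.micro_trajectory <- function(x, ...) {
  dplyr::bind_rows(purrr::map2(x$frames, x$times,
                               function(f, t) dplyr::mutate(f, t = t)))
}
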