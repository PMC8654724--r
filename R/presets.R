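#' Experiment presets
#'
#' Ready-made configurations of the package's paired micro/macro
#' experiments.  Each returns a plain list of the generator, force and
#' solver parameters; pass it to [run_paired_cbm_1d()],
#' [run_wo_1d()] or [run_paired_cbm_2d()].
#'
#' * `preset_cbm_1d_peak()`: 40 cells on `[0, 37]` with a smooth central
#'   density peak (profile mass = N so the equilibrium density is 1);
#'   exponential center-based forces, `dt = 1.25e-4` to `t = 0.1`, grid
#'   spacing 1.95.  The peak lies in the repulsive regime and diffuses
#'   away in both models.
#' * `preset_cbm_1d_lowdensity()`: 40 cells on `[0, 47]` with a central
#'   depletion down to density 0.5, `dt = 1e-3` to `t = 3`, grid
#'   spacing 2.50.  Low densities enter the band where the
#'   coarse-grained diffusion coefficient is negative, so the PDE
#'   develops persistent oscillations that the discrete model does not
#'   show.
#' * `preset_wo_1d_peak()`: 39 Weliky-Oster cells on `[0.5, 36.5]` with
#'   the same peak shape, `sigma = 50`, `dt = 4e-4` to `t = 0.4`, grid
#'   spacing 1.90; the Weliky-Oster diffusion is positive, so both
#'   levels relax monotonically.
#' * `preset_cbm_2d_radial()`: ~1778 cells in a hexagonal pattern on
#'   `[0, 40]^2` at outer density 1.15, radially compressed at the
#'   center to density ~1.9; exponential forces, `dt = 2.5e-4` to
#'   `t = 0.45`; the macro grid covers the interior window `[8, 32]^2`
#'   with spacing 1.263 so the frozen micro boundary does not
#'   contaminate the comparison.
#'
#' @return a named list of parameters.
#' @name presets
NULL

#' @rdname presets
#' @export
preset_cbm_1d_peak <- function() {
  list(domain = sim_domain(0, 37), N = 40, base_density = 1,
       center = 18.5, width = 5, amplitude = 0.6,
       force = exp_force(), dt = 1.25e-4, T = 0.1, dx = 1.95)
}

#' @rdname presets
#' @export
preset_cbm_1d_lowdensity <- function() {
  list(domain = sim_domain(0, 47), N = 40, base_density = 1,
       center = 23.5, width = 14, amplitude = -0.5,
       force = exp_force(), dt = 1e-3, T = 3, dx = 2.50)
}

#' @rdname presets
#' @export
preset_wo_1d_peak <- function() {
  list(domain = sim_domain(0.5, 36.5), N = 39, base_density = 1,
       center = 18.5, width = 5, amplitude = 0.6,
       sigma = 50, dt = 4e-4, T = 0.4, dx = 1.90)
}

#' @rdname presets
#' @export
preset_cbm_2d_radial <- function() {
  list(domain = sim_domain(c(0, 0), c(40, 40)),
       h = sqrt(2 / (sqrt(3) * 1.15)),
       center = c(20, 20), radius = 8, factor = 1.65,
       force = exp_force(), dt = 2.5e-4, T = 0.45,
       grid_domain = sim_domain(c(8, 8), c(32, 32)), dx = 1.263, J = 6)
}

#' Paired 1D center-based micro/macro experiment
#'
#' Generates the initial centers from the preset profile, runs the
#' center-based micro model and the finite-volume macro model with the
#' coarse-grained pressure law from the same force, and compares the two
#' densities at each saved time.
#'
#' @param preset a list as returned by [preset_cbm_1d_peak()] or
#'   [preset_cbm_1d_lowdensity()].
#' @param save_every snapshot stride in steps (default: 5 frames per
#'   run).
#' @return list with `micro` (a `micro_trajectory`), `macro`
#'   (a `macro_trajectory`), `metrics` (tibble of per-frame
#'   [compare_density()] rows) and `preset`.
#' @export
run_paired_cbm_1d <- function(preset, save_every = NULL) {
  n_steps <- round(preset$T / preset$dt)
  if (is.null(save_every)) save_every <- max(1, n_steps %/% 4)
  ic <- ic_profile_1d(preset$N, preset$domain, preset$base_density,
                      preset$center, preset$width, preset$amplitude)
  state <- micro_state_cbm(ic, preset$domain, frozen = ic$frozen)
  micro <- run_micro(state, preset$force, preset$dt, preset$T,
                     save_every = save_every)
  grid <- suppressWarnings(build_grid(preset$domain, preset$dx))
  field0 <- micro_to_grid(micro$frames[[1]], grid)
  law <- pressure_law_cbm(preset$force, d = 1)
  macro <- run_macro(field0, law, preset$dt, preset$T,
                     save_every = save_every)
  metrics <- paired_metrics(micro, macro)
  list(micro = micro, macro = macro, metrics = metrics, preset = preset)
}

#' Paired 1D Weliky-Oster micro/macro experiment
#'
#' The 1D Weliky-Oster micro model moves cell boundaries with velocity
#' `sigma (rho_left - rho_right)`; the macro model uses the i-dependent
#' discrete pressure scheme [fvm_step_wo_1d()].
#'
#' @param preset a list as returned by [preset_wo_1d_peak()].
#' @inheritParams run_paired_cbm_1d
#' @return as [run_paired_cbm_1d()].
#' @export
run_wo_1d <- function(preset, save_every = NULL) {
  n_steps <- round(preset$T / preset$dt)
  if (is.null(save_every)) save_every <- max(1, n_steps %/% 4)
  ic <- ic_profile_1d(preset$N, preset$domain, preset$base_density,
                      preset$center, preset$width, preset$amplitude)
  tess <- tessellate_1d(ic, preset$domain)
  micro <- run_wo_micro_1d(tess, preset$sigma, preset$dt, preset$T,
                           save_every)
  grid <- suppressWarnings(build_grid(preset$domain, preset$dx))
  field0 <- micro_to_grid(micro$frames[[1]], grid)
  macro <- run_macro(field0, dt = preset$dt, T = preset$T,
                     save_every = save_every, scheme = "wo_1d",
                     sigma = preset$sigma)
  metrics <- paired_metrics(micro, macro)
  list(micro = micro, macro = macro, metrics = metrics, preset = preset)
}

# 1D Weliky-Oster micro model: state is the vector of cell boundaries
# (nodes); interior nodes move with sigma (1/V_left - 1/V_right), end
# nodes are fixed.
run_wo_micro_1d <- function(tess, sigma, dt, T, save_every) {
  xs <- sort(tess$cells$x)
  b <- c(tess$domain$lower, (xs[-length(xs)] + xs[-1]) / 2, tess$domain$upper)
  n_steps <- round(T / dt)
  snap <- function(b, t) {
    V <- diff(b)
    tibble(cell = seq_along(V), x = (b[-1] + b[-length(b)]) / 2,
           V = V, rho = 1 / V)
  }
  frames <- list(snap(b, 0)); times <- 0
  nb <- length(b)
  for (n in seq_len(n_steps)) {
    V <- diff(b)
    if (any(V <= 0)) abort(sprintf("step %d collapsed a cell; use a smaller dt.", n))
    v <- sigma * (1 / V[-length(V)] - 1 / V[-1])
    b[2:(nb - 1)] <- b[2:(nb - 1)] + dt * v
    if (n %% save_every == 0 || n == n_steps) {
      frames[[length(frames) + 1]] <- snap(b, n * dt)
      times <- c(times, n * dt)
    }
  }
  structure(list(frames = frames, times = times, final = NULL,
                 manifest = list(kind = "wo_1d", dt = dt, T = T,
                                 n_steps = n_steps, save_every = save_every)),
            class = "micro_trajectory")
}

#' Paired 2D center-based micro/macro experiment
#'
#' Hexagonal-lattice cells with a central radial disturbance, integrated
#' with per-step re-tessellation, against the finite-volume solution of
#' the coarse-grained pressure law on an interior Cartesian window.
#'
#' @param preset a list as returned by [preset_cbm_2d_radial()].
#' @param save_every snapshot stride in steps.
#' @return as [run_paired_cbm_1d()], plus `averages`: the
#'   omega-weighted mean densities of the interpolated micro and the
#'   macro fields over the window at the final time.
#' @export
run_paired_cbm_2d <- function(preset, save_every = NULL) {
  n_steps <- round(preset$T / preset$dt)
  if (is.null(save_every)) save_every <- max(1, n_steps %/% 4)
  ic <- ic_hex_2d(preset$domain, preset$h, preset$center, preset$radius,
                  preset$factor)
  state <- micro_state_cbm(ic, preset$domain)
  micro <- run_micro(state, preset$force, preset$dt, preset$T,
                     save_every = save_every, retessellate_every = 1)
  grid <- suppressWarnings(build_grid(preset$grid_domain, preset$dx))
  field0 <- micro_to_grid(micro$frames[[1]], grid)
  law <- pressure_law_cbm(preset$force, d = 2, J = preset$J)
  macro <- run_macro(field0, law, preset$dt, preset$T,
                     save_every = save_every)
  metrics <- paired_metrics(micro, macro)
  mi_final <- micro_to_grid(micro$frames[[length(micro$frames)]], grid)
  averages <- tibble(
    micro = mean(mi_final$rho),
    macro = mean(macro$final$rho))
  list(micro = micro, macro = macro, metrics = metrics,
       averages = averages, preset = preset)
}

paired_metrics <- function(micro, macro) {
  kmax <- min(length(micro$frames), length(macro$frames))
  dplyr::bind_rows(lapply(seq_len(kmax), function(k)
    dplyr::mutate(
      compare_density(micro$frames[[k]], macro$frames[[k]]),
      t = macro$times[k], .before = 1)))
}
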