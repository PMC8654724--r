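test_that("grids carry exact element geometry and adjust inexact spacings", {
  g <- build_grid(sim_domain(0, 1), 0.25)
  expect_equal(g$n, 4L)
  expect_equal(g$omega, 0.25)
  expect_equal(g$centers$x, c(0.125, 0.375, 0.625, 0.875))
  g2 <- build_grid(sim_domain(c(0, 0), c(1, 1)), 0.5)
  expect_equal(g2$n, c(2L, 2L))
  expect_equal(g2$omega, 0.25)
  # an inexact spacing is snapped to the nearest divisor with a note
  expect_warning(g3 <- build_grid(sim_domain(0, 37), 1.95), "adjusted")
  expect_equal(g3$n, 19L)
  expect_equal(g3$dx, 37 / 19)
  expect_length(g3$notes, 1)
  expect_error(build_grid(sim_domain(0, 1), -0.1), "positive")
})

test_that("uniform fields are fixed points and mass is conserved exactly", {
  law <- pressure_law_power(1, 2)
  g <- build_grid(sim_domain(0, 10), 0.5)
  fu <- grid_field(g, rep(1.3, 20))
  expect_equal(fvm_step(fu, law, 1e-3)$rho, rep(1.3, 20))
  withr::with_seed(8, f <- grid_field(g, 0.8 + 0.4 * runif(20)))
  m0 <- total_mass(f)
  expect_equal(m0, g$omega * sum(f$rho))
  f1 <- fvm_step(f, law, 1e-3)
  expect_equal(total_mass(f1), m0, tolerance = 1e-13)
  expect_false(isTRUE(all.equal(f1$rho, f$rho)))
})

test_that("the explicit step reproduces a two-element hand computation", {
  g <- ref_force()
  law <- pressure_law_cbm(g, d = 1)
  grid <- build_grid(sim_domain(0, 2), 1)
  f <- grid_field(grid, c(1, 1.25))
  dt <- 1e-3
  out <- fvm_step(f, law, dt)
  p1 <- 0 # rest volume
  p2 <- -(1 / 50) * 0.8 * force_g(g, 0.8)
  drho <- 50 * dt * 0.5 * (1 + 1.25) * (p2 - p1) # mu dt rho_ij (p2-p1)/l * sigma
  expect_equal(out$rho, c(1 + drho, 1.25 - drho), tolerance = 1e-14)
})

test_that("mirror-symmetric data stay mirror-symmetric", {
  law <- pressure_law_cbm(ref_force(), d = 1)
  grid <- build_grid(sim_domain(0, 10), 0.5)
  x <- grid$centers$x
  f <- grid_field(grid, 1 + 0.4 * exp(-(x - 5)^2))
  tr <- run_macro(f, law, 1e-4, 0.05)
  fin <- tr$final$rho
  expect_equal(fin, rev(fin), tolerance = 1e-12)
})

test_that("the specialized 1D center-based scheme equals the generic step", {
  g <- ref_force()
  law <- pressure_law_cbm(g, d = 1)
  grid <- build_grid(sim_domain(0, 12), 0.75)
  withr::with_seed(15, rho <- 0.9 + 0.5 * runif(16))
  f <- grid_field(grid, rho)
  a <- fvm_step(f, law, 2e-4)
  b <- fvm_step_cbm_1d(f, g, 2e-4)
  expect_equal(a$rho, b$rho, tolerance = 1e-13)
  expect_equal(fvm_step_cbm_1d(grid_field(grid, rep(1.1, 16)), g, 1e-3)$rho,
               rep(1.1, 16))
})

test_that("the 1D Weliky-Oster scheme diffuses with a second-order mass defect", {
  grid <- build_grid(sim_domain(0, 6), 0.5)
  x <- grid$centers$x
  rho <- 1 + 0.3 * cos(pi * x / 6)
  f <- grid_field(grid, rho)
  # uniform field unchanged
  expect_equal(fvm_step_wo_1d(grid_field(grid, rep(2, 12)), 50, 1e-4)$rho,
               rep(2, 12))
  # three-element hand expansion
  g3 <- build_grid(sim_domain(0, 3), 1)
  f3 <- grid_field(g3, c(1, 2, 1.5))
  s <- 10; dt <- 1e-3
  out <- fvm_step_wo_1d(f3, s, dt)
  fV <- s * c(1, 2, 1.5)
  r1 <- 1 + dt * (0.5 * (1 + 2) * 1 * (fV[2] - fV[1]))
  r2 <- 2 + dt * (0.5 * (2 + 1.5) * 0.5 * (fV[3] - fV[2]) +
                    0.5 * (1 + 2) * 0.5 * (fV[1] - fV[2]))
  r3 <- 1.5 + dt * (0.5 * (1.5 + 2) * (2 / 3) * (fV[2] - fV[3]))
  expect_equal(out$rho, c(r1, r2, r3), tolerance = 1e-14)
  # variance decreases (positive diffusion) for small dt
  f1 <- fvm_step_wo_1d(f, 50, 1e-5)
  dev <- function(z) sum(grid$omega * (z - mean(z))^2)
  expect_lt(dev(f1$rho), dev(f$rho))
  # the scheme's mass defect is second order in the density contrasts
  drift <- function(eps) {
    fe <- grid_field(grid, 1 + eps * cos(pi * x / 6))
    tr <- run_macro(fe, dt = 1e-5, T = 2e-3, scheme = "wo_1d", sigma = 50)
    tr$manifest$mass_drift
  }
  d1 <- drift(0.2); d2 <- drift(0.1)
  expect_lt(d1, 1e-3)
  expect_equal(d1 / d2, 4, tolerance = 0.25) # quadratic in the contrast
})

test_that("grid refinement shows second-order spatial convergence on a smooth flow", {
  law <- pressure_law_power(1, 2)
  run_n <- function(n, dt, T) {
    g <- build_grid(sim_domain(0, 1), 1 / n)
    rho <- 1 + 0.1 * cos(pi * g$centers$x)
    run_macro(grid_field(g, rho), law, dt, T)$final
  }
  dt <- 2e-6; T <- 4e-3
  ref <- run_n(320, dt, T)
  err <- vapply(c(40, 80, 160), function(n) {
    sol <- run_n(n, dt, T)
    # smooth (4th-order) restriction of the reference; compare away from
    # the walls so the comparison error stays below the scheme error
    ref_at <- spline(ref$grid$centers$x, ref$rho,
                     xout = sol$grid$centers$x, method = "fmm")$y
    keep <- sol$grid$centers$x > 0.1 & sol$grid$centers$x < 0.9
    max(abs(sol$rho - ref_at)[keep])
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_gt(min(orders), 1.8)
})

test_that("macro runs are deterministic with manifest bookkeeping", {
  law <- pressure_law_power(1, 2)
  g <- build_grid(sim_domain(0, 5), 0.25)
  withr::with_seed(3, f <- grid_field(g, 1 + 0.2 * runif(20)))
  t1 <- run_macro(f, law, 1e-4, 0.01, save_every = 25)
  t2 <- run_macro(f, law, 1e-4, 0.01, save_every = 25)
  expect_identical(t1$final$rho, t2$final$rho)
  expect_length(run_macro(f, law, 1e-4, 0)$frames, 1)
  expect_lt(t1$manifest$mass_drift, 1e-13)
  expect_true(is.finite(t1$manifest$dt_stable_estimate))
  gl <- glance(t1)
  expect_equal(gl$n_steps, 100)
  td <- tidy(t1$final)
  expect_equal(nrow(td), 20)
})
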