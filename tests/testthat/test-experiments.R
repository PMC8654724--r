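test_that("1D initial profiles realize the requested density shape", {
  dom <- sim_domain(0, 37)
  # zero amplitude: equispaced centers
  ic0 <- ic_profile_1d(40, dom, 1, 18.5, 5, 0)
  expect_equal(diff(ic0$x), rep(37 / 40, 39), tolerance = 1e-9)
  expect_equal(ic0$frozen, seq_len(40) %in% c(1, 40))
  # central peak: maximum density at the central cell, one-sided monotone
  ic <- ic_profile_1d(40, dom, 1, 18.5, 5, 0.6)
  tt <- tessellate_1d(ic, dom)
  rho <- tt$cells$rho
  k <- which.max(rho)
  expect_lt(abs(tt$cells$x[k] - 18.5), 1.5)
  expect_true(all(diff(rho[1:k]) >= -1e-9))
  expect_true(all(diff(rho[k:length(rho)]) <= 1e-9))
  # profile tracked within 2% away from the domain ends
  mid <- which(ic$x > 3 & ic$x < 34)
  target <- 1 + ifelse(abs(ic$x - 18.5) < 5,
                       0.6 * cos(pi * (ic$x - 18.5) / 10)^2, 0)
  expect_lt(max(abs(rho[mid] / target[mid] - 1)), 0.02)
  # deterministic regeneration
  expect_identical(ic, ic_profile_1d(40, dom, 1, 18.5, 5, 0.6))
  # impossible profile is rejected
  expect_error(ic_profile_1d(40, dom, 1, 18.5, 5, -1.2), "non-positive")
})

test_that("hexagonal 2D initial conditions hit the reference regime", {
  p <- preset_cbm_2d_radial()
  # undisturbed lattice: uniform density 2/(sqrt(3) h^2) away from walls
  flat <- ic_hex_2d(p$domain, p$h)
  tf <- tessellate_2d(flat, p$domain, mesh = FALSE, polygons = FALSE)
  i_int <- deep_cells(tf, margin = 2 * p$h) # skip the ragged wall layer
  expect_equal(tf$cells$rho[i_int],
               rep(2 / (sqrt(3) * p$h^2), length(i_int)), tolerance = 1e-9)
  # disturbance factor 1 is the identity
  expect_identical(flat, ic_hex_2d(p$domain, p$h, p$center, p$radius, 1))
  # full preset: cell count within 5% of 1777 and central density in range
  ic <- ic_hex_2d(p$domain, p$h, p$center, p$radius, p$factor)
  expect_lt(abs(nrow(ic) - 1777) / 1777, 0.05)
  td <- tessellate_2d(ic, p$domain, mesh = FALSE, polygons = FALSE)
  r2 <- (ic$x - 20)^2 + (ic$y - 20)^2
  rho_c <- td$cells$rho[which.min(r2)]
  expect_gt(rho_c, 1.11)
  expect_lt(rho_c, 1.97)
  # density radially non-increasing (binned) over the inner disturbance
  rr <- sqrt(r2)
  bins <- cut(rr[rr < 0.75 * p$radius], breaks = 6)
  prof <- tapply(td$cells$rho[rr < 0.75 * p$radius], bins, mean)
  expect_true(all(diff(prof) < 0.02))
})

test_that("micro-to-grid interpolation is exact on linear data and near-conservative", {
  g1 <- build_grid(sim_domain(0, 10), 0.5)
  s_const <- tibble::tibble(x = seq(0.25, 9.75, by = 0.5), rho = 2)
  expect_equal(micro_to_grid(s_const, g1)$rho, rep(2, 20))
  s_lin <- tibble::tibble(x = seq(0.1, 9.9, length.out = 30))
  s_lin$rho <- 0.5 + 0.2 * s_lin$x
  expect_equal(micro_to_grid(s_lin, g1)$rho, 0.5 + 0.2 * g1$centers$x,
               tolerance = 1e-12)
  expect_error(micro_to_grid(s_lin[0, ], g1), "empty")

  # 2D: smooth samples on a perturbed lattice; interpolant conserves the
  # sampled mass over the window within 2%
  hx <- perturbed_hex(h = 1, L = 12, sd = 0.02, seed = 31)
  tt <- tessellate_2d(hx$centers, hx$domain, mesh = FALSE)
  sm <- cell_density(tt)
  sm$rho <- 1 + 0.3 * exp(-((sm$x - 6)^2 + (sm$y - 6)^2) / 8)
  g2 <- build_grid(sim_domain(c(2, 2), c(10, 10)), 0.5)
  fld <- micro_to_grid(sm, g2)
  # linear 2D data are reproduced exactly as well
  sl <- sm
  sl$rho <- 0.2 + 0.05 * sl$x + 0.03 * sl$y
  fl <- micro_to_grid(sl, g2)
  expect_equal(fl$rho, 0.2 + 0.05 * g2$centers$x + 0.03 * g2$centers$y,
               tolerance = 1e-9)
  mass_grid <- total_mass(fld)
  exact <- function(x, y) 1 + 0.3 * exp(-((x - 6)^2 + (y - 6)^2) / 8)
  xs <- seq(2.005, 9.995, length.out = 200)
  mass_true <- mean(outer(xs, xs, exact)) * 64
  expect_lt(abs(mass_grid - mass_true) / mass_true, 0.02)
})

test_that("line profiles slice 2D fields along constant y", {
  g <- build_grid(sim_domain(c(0, 0), c(4, 2)), 0.5)
  f <- grid_field(g, g$centers$x + 10 * g$centers$y)
  pr <- line_profile(f, 0.8)
  expect_equal(nrow(pr), 8) # one value per x element
  expect_equal(pr$rho, pr$x + 10 * 0.75) # nearest row center
  fc <- grid_field(g, rep(3, 32))
  expect_equal(line_profile(fc, 1)$rho, rep(3, 8))
  expect_error(line_profile(f, 5), "outside")
})

test_that("comparison metrics vanish on identical inputs and detect offsets", {
  g <- build_grid(sim_domain(0, 10), 0.5)
  samples <- tibble::tibble(x = seq(0.25, 9.75, by = 0.5), rho = 1.5)
  f <- grid_field(g, rep(1.5, 20))
  m <- compare_density(samples, f)
  expect_equal(m$linf, 0)
  expect_equal(m$l2, 0)
  expect_equal(m$mass_diff, 0)
  f2 <- grid_field(g, rep(1.25, 20))
  m2 <- compare_density(samples, f2)
  expect_equal(m2$linf, 0.25)
  expect_equal(m2$mass_diff, 0.25 * 10)
  expect_error(compare_density(samples, f, sim_domain(20, 30)), "overlap")
})

test_that("configuration files round-trip and rebuild the model objects", {
  cfg <- list(
    force = list(cbm_exp = list(mu = 50, s = 1, c = 10, r_A = 1.5),
                 wo = list(sigma = 50, kappa = 1)),
    pressure = list(kind = "cbm", d = 1, J = 2, mu = 50))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$force$cbm_exp$mu, 50)
  laws <- laws_from_config(back)
  expect_s3_class(laws$cbm_exp, "force_law")
  expect_s3_class(laws$wo, "wo_params")
  expect_s3_class(laws$pressure, "pressure_law")
  expect_equal(cbm_pressure(1.2, laws$pressure),
               cbm_pressure(1.2, pressure_law_cbm(exp_force(), 1)))
})

test_that("plot builders return ggplot objects", {
  dom <- sim_domain(c(0, 0), c(6, 6))
  tt <- tessellate_2d(random_centers(20, dom, seed = 2), dom, mesh = FALSE)
  expect_s3_class(autoplot(tt), "ggplot")
  t1 <- tessellate_1d(data.frame(x = c(1, 2, 3.5)), sim_domain(0, 5))
  expect_s3_class(autoplot(t1), "ggplot")
  g <- build_grid(sim_domain(c(0, 0), c(4, 4)), 0.5)
  f <- grid_field(g, rep(1, 64))
  expect_s3_class(autoplot(f), "ggplot")
  sm <- tibble::tibble(x = runif(10, 0, 4), y = runif(10, 0, 4), rho = 1)
  expect_s3_class(plot_density_comparison(sm, f, y = 2), "ggplot")
})
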