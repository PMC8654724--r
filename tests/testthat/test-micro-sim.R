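test_that("center-based stepping honors equilibria, frozen cells and the scalar oracle", {
  g <- ref_force()
  dom <- sim_domain(0, 10)
  # equilibrium chain at rest spacing: a fixed point
  chain <- data.frame(x = seq(1.5, 8.5, by = 1))
  st <- micro_state_cbm(chain, dom, frozen = rep(FALSE, 8))
  st1 <- step_cbm(st, g, 1e-3)
  expect_equal(st1$coords, st$coords, tolerance = 1e-14)
  # dt = 0 is the identity
  expect_identical(step_cbm(st, g, 0)$coords, st$coords)
  # free middle cell between frozen neighbors, 1.2 to its left and 1.1
  # to its right: it drifts toward the nearer (stronger) adhesion
  st2 <- micro_state_cbm(data.frame(x = c(4, 5.2, 6.3)), dom,
                         frozen = c(TRUE, FALSE, TRUE))
  dt <- 2e-4
  out <- step_cbm(st2, g, dt)
  expect_equal(unname(out$coords[2, 1] - 5.2),
               dt * (5 * exp(-1) - 10 * exp(-2)), tolerance = 1e-12)
  expect_equal(unname(out$coords[c(1, 3), 1]), c(4, 6.3)) # frozen cells fixed
  # a reordering step is rejected with a dt hint
  st3 <- micro_state_cbm(data.frame(x = c(4, 4.2, 6)), dom,
                         frozen = rep(FALSE, 3))
  expect_error(step_cbm(st3, g, 1), "smaller dt")
})

test_that("free center-based systems conserve their center of mass", {
  g <- ref_force()
  dom <- sim_domain(c(0, 0), c(12, 12))
  ctr <- random_centers(30, sim_domain(c(0, 0), c(8, 8)), seed = 9)
  ctr <- dplyr::mutate(ctr, x = x + 2, y = y + 2)
  st <- micro_state_cbm(ctr, dom, frozen = rep(FALSE, 30))
  com0 <- colSums(st$coords)
  for (i in 1:50) st <- step_cbm(st, g, 5e-4)
  expect_equal(colSums(st$coords), com0, tolerance = 1e-8)
})

test_that("micro runs are deterministic and relax a 1D density peak monotonically", {
  p <- preset_cbm_1d_peak()
  ic <- ic_profile_1d(p$N, p$domain, p$base_density, p$center, p$width,
                      p$amplitude)
  st <- micro_state_cbm(ic, p$domain, frozen = ic$frozen)
  tr1 <- run_micro(st, p$force, p$dt, 0.02, save_every = 40)
  tr2 <- run_micro(st, p$force, p$dt, 0.02, save_every = 40)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$final$coords, tr2$final$coords)
  maxr <- vapply(tr1$frames, function(f) max(f$rho), numeric(1))
  expect_true(all(diff(maxr) <= 1e-12))
  # T = 0 gives a single frame
  expect_length(run_micro(st, p$force, p$dt, 0)$frames, 1)
})

test_that("per-cell density is the reciprocal volume with exact mass identity", {
  dom <- sim_domain(0, 5)
  st <- micro_state_cbm(data.frame(x = seq(0.5, 4.5, by = 1)), dom)
  df <- density_field(st)
  expect_equal(df$rho, rep(1, 5))
  expect_equal(sum(df$V * df$rho), 5) # sum V_i rho_i = N exactly
  hx <- perturbed_hex(h = 1, L = 8, sd = 0)
  sth <- micro_state_cbm(hx$centers, hx$domain)
  dfh <- density_field(sth)
  i_int <- deep_cells(sth$tess, margin = 2)
  expect_equal(dfh$rho[i_int], rep(2 / sqrt(3), length(i_int)),
               tolerance = 1e-9)
})

test_that("the geometric-conservation-law update matches re-tessellation in 1D", {
  g <- ref_force()
  p <- preset_cbm_1d_peak()
  ic <- ic_profile_1d(p$N, p$domain, 1, p$center, p$width, p$amplitude)
  st <- micro_state_cbm(ic, p$domain, frozen = ic$frozen)
  # zero-force configuration leaves volumes unchanged
  eq <- micro_state_cbm(data.frame(x = seq(0.5, 36.5, by = 1)),
                        sim_domain(0, 37))
  expect_equal(gcl_volume_update(eq, g, 1e-3), eq$tess$cells$V)
  # flux increments telescope to zero
  dt <- 1e-4
  Vg <- gcl_volume_update(st, g, dt)
  expect_equal(sum(Vg), sum(st$tess$cells$V), tolerance = 1e-10)
  # in 1D the midpoint interfaces move at the mean neighbor velocity, so
  # the flux update reproduces the re-tessellated volumes to round-off
  st1 <- step_cbm(st, g, dt)
  V_retess <- tessellate_1d(data.frame(x = st1$coords[, 1]), p$domain)$cells$V
  expect_equal(Vg, V_retess, tolerance = 1e-12)
})

test_that("vertex-model steps preserve the tiling and reject collapse", {
  hx <- perturbed_hex(h = 1, L = 8, sd = 0.03, seed = 13)
  mesh <- tessellate_2d(hx$centers, hx$domain)$mesh
  st <- micro_state_vbm(mesh)
  wp <- wo_params(1, 1)
  # dt = 0 identity
  expect_identical(step_vbm(st, wp, 0)$mesh$vertices, st$mesh$vertices)
  s1 <- step_vbm(st, wp, 1e-4)
  # frozen (boundary) vertices never move
  bnd <- st$mesh$vertices$boundary
  expect_identical(s1$mesh$vertices$x[bnd], st$mesh$vertices$x[bnd])
  # moved polygons still tile the domain: total area is invariant
  expect_equal(sum(s1$stats$V), sum(st$stats$V), tolerance = 1e-10)
  # one cell's new area agrees with an independent shoelace evaluation
  k <- which(!tessellate_2d(hx$centers, hx$domain)$cells$boundary)[1]
  ring <- s1$mesh$cells[[k]]
  xx <- s1$mesh$vertices$x[ring]; yy <- s1$mesh$vertices$y[ring]
  sho <- 0.5 * abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy))
  expect_equal(s1$stats$V[k], sho, tolerance = 1e-12)
  # the uniform hexagonal core is invariant (border rows feel the walls)
  mesh0 <- tessellate_2d(perturbed_hex(h = 1, L = 8, sd = 0)$centers,
                         sim_domain(c(0, 0), c(8, 8)))$mesh
  st0 <- micro_state_vbm(mesh0)
  deep <- deep_hex_vertices(mesh0, st0$stats)
  s0 <- step_vbm(st0, wp, 1e-3)
  expect_equal(s0$mesh$vertices$x[deep], st0$mesh$vertices$x[deep],
               tolerance = 1e-12)
  expect_equal(s0$mesh$vertices$y[deep], st0$mesh$vertices$y[deep],
               tolerance = 1e-12)
  # an absurd timestep is rejected rather than producing a broken mesh
  expect_error(step_vbm(st, wp, 10), "dt")
})
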