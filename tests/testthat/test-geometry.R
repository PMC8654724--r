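test_that("1D tessellation spans midpoints, clips at the domain and keeps order", {
  dom <- sim_domain(0, 3)
  t1 <- tessellate_1d(data.frame(x = c(0.5, 1.5, 2.5)), dom)
  expect_equal(t1$cells$V, c(1, 1, 1))
  expect_equal(sort(t1$neighbors$j[t1$neighbors$i == 2]), c(1, 3))
  expect_true(all(t1$neighbors$a_ij == 1))

  t2 <- tessellate_1d(data.frame(x = c(0.5, 1.0, 2.5)), dom)
  expect_equal(t2$cells$V, c(0.75, 1.0, 1.25)) # midpoints 0.75 and 1.75
  expect_equal(sum(t2$cells$V), 3)

  # original indexing is preserved through sorting
  t3 <- tessellate_1d(data.frame(x = c(2.5, 0.5, 1.0)), dom)
  expect_equal(t3$cells$V, c(1.25, 0.75, 1.0))
  expect_equal(t3$order, c(2L, 3L, 1L))

  expect_error(tessellate_1d(data.frame(x = c(1, 1)), dom), "duplicate")
  expect_error(tessellate_1d(data.frame(x = c(-1, 2)), dom), "outside")
})

test_that("2D tessellation partitions the domain with symmetric adjacency", {
  dom <- sim_domain(c(0, 0), c(7, 5))
  ctr <- random_centers(60, dom, seed = 11)
  tt <- tessellate_2d(ctr, dom, mesh = FALSE)
  expect_equal(sum(tt$cells$V), 35, tolerance = 1e-10)
  nb <- tt$neighbors
  # j in J_i <=> i in J_j with equal interface measure
  key <- paste(nb$i, nb$j)
  rkey <- paste(nb$j, nb$i)
  expect_true(all(rkey %in% key))
  m <- match(rkey, key)
  expect_equal(nb$a_ij, nb$a_ij[m])
  expect_equal(nb$a_ij[m], nb$a_ij, tolerance = 1e-12)
  # perimeter of interior cells = sum of its interface measures
  per <- tapply(nb$a_ij, nb$i, sum)
  int_ <- which(!tt$cells$boundary)
  expect_equal(as.numeric(per[as.character(int_)]), tt$cells$a[int_],
               tolerance = 1e-9)
  # Voronoi edges are perpendicular bisectors: n_ij is parallel to rhat_ij
  m2 <- as.matrix(ctr)
  dx <- m2[nb$j, 1] - m2[nb$i, 1]; dy <- m2[nb$j, 2] - m2[nb$i, 2]
  r <- sqrt(dx^2 + dy^2)
  expect_lt(max(abs(nb$nx - dx / r) + abs(nb$ny - dy / r)), 1e-10)
})

test_that("2D tessellation handles the four-square and hexagon references", {
  dom <- sim_domain(c(0, 0), c(1, 1))
  tt <- tessellate_2d(data.frame(x = c(0.25, 0.75, 0.25, 0.75),
                                 y = c(0.25, 0.25, 0.75, 0.75)), dom)
  expect_equal(tt$cells$V, rep(0.25, 4), tolerance = 1e-12)
  expect_true(tt$mesh$degenerate) # central vertex is 4-valent

  hx <- perturbed_hex(h = 1, L = 12, sd = 0) # exact lattice
  tt <- tessellate_2d(hx$centers, hx$domain, mesh = FALSE)
  i_int <- deep_cells(tt, margin = 2) # away from the clipped border rows
  expect_gt(length(i_int), 50)
  expect_equal(tt$cells$V[i_int], rep(sqrt(3) / 2, length(i_int)),
               tolerance = 1e-9)
  expect_true(all(tt$cells$n_neighbors[i_int] == 6))

  expect_error(tessellate_2d(data.frame(x = 1:5, y = 1:5),
                             sim_domain(c(0, 0), c(6, 6))), "collinear")
  expect_error(tessellate_2d(data.frame(x = 1:2, y = c(1, 1)),
                             sim_domain(c(0, 0), c(6, 6))), "at least 3")
})

test_that("a regular-polygon cell reproduces the closed-form area/edge relations", {
  # one center ringed by J = 6 equidistant centers: the central Voronoi
  # cell is a regular hexagon with inradius h/2
  h <- 1.4
  th <- 2 * pi * (0:5) / 6
  ctr <- data.frame(x = c(10, 10 + h * cos(th)), y = c(10, 10 + h * sin(th)))
  tt <- tessellate_2d(ctr, sim_domain(c(0, 0), c(20, 20)), mesh = FALSE)
  r_i <- h / 2
  J <- 6
  expect_equal(tt$cells$V[1], J * r_i^2 * tan(pi / J), tolerance = 1e-8)
  aij <- tt$neighbors$a_ij[tt$neighbors$i == 1]
  expect_equal(aij, rep(2 * r_i * tan(pi / J), J), tolerance = 1e-8)
  expect_equal(tt$cells$a[1], 2 * r_i * J * tan(pi / J), tolerance = 1e-8)
  expect_equal(tt$cells$r_in[1], r_i, tolerance = 1e-10)
})

test_that("xi factors match their closed forms, limits and monotonicity", {
  expect_equal(xi_factor(1), 0.5)
  expect_equal(round(xi_factor(2, c(3, 4, 5, 6)), 4),
               c(0.4387, 0.5000, 0.5247, 0.5373))
  expect_equal(xi_factor(2, Inf), 1 / sqrt(pi))
  expect_equal(round(xi_factor(3, c(4, 6, 8, 12)), 4),
               c(0.4163, 0.5000, 0.5246, 0.5648))
  expect_equal(xi_factor(3, Inf), (3 / (4 * pi))^(1 / 3))
  xs <- xi_factor(2, 3:64)
  expect_true(all(diff(xs) > 0))
  expect_true(all(xs < 1 / sqrt(pi)))
  x3 <- xi_factor(3, c(4, 6, 8, 12, 100))
  expect_true(all(diff(x3) > 0))
  expect_error(xi_factor(2, 2), "J")
  expect_equal(xi_factor(3, 10, xi_override = 0.549), 0.549)
})

test_that("shape relations tie inradius, interface and perimeter to the volume", {
  sq <- shape_relations(2, 4, 4)
  expect_equal(sq$r, 1) # inradius of a square of area 4
  one_d <- shape_relations(1, 2, 2)
  expect_equal(one_d$r, 1)
  expect_equal(one_d$V_over_aij, 2)
  expect_equal(one_d$a, 2)
  hexa <- shape_relations(2, 6, 1)
  expect_equal(round(hexa$a, 4), round(2 / xi_factor(2, 6), 4))
  expect_equal(round(hexa$a, 4), 3.7224, tolerance = 1e-3)
  expect_error(shape_relations(2, 6, -1), "positive")
})

test_that("vertex meshes of generic point sets are 3-valent with consistent incidence", {
  hx <- perturbed_hex(h = 1, L = 8, sd = 0.03, seed = 7)
  tt <- tessellate_2d(hx$centers, hx$domain)
  mesh <- tt$mesh
  expect_false(mesh$degenerate)
  int_v <- which(!mesh$vertices$boundary)
  expect_gt(length(int_v), 20)
  expect_true(all(lengths(mesh$incident_cells[int_v]) == 3))
  expect_true(all(lengths(mesh$adjacency[int_v]) == 3))
  # mesh polygon areas agree with the tessellation's cell areas
  st <- mesh_cell_stats(mesh)
  expect_equal(st$V, tt$cells$V, tolerance = 1e-9)
  expect_equal(st$a, tt$cells$a, tolerance = 1e-9)
})

test_that("tessellation summaries round-trip through CSV", {
  dom <- sim_domain(c(0, 0), c(7, 5))
  ctr <- random_centers(25, dom, seed = 4)
  tt <- tessellate_2d(ctr, dom, mesh = FALSE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_centers_csv(ctr, f1)
  back <- read_centers_csv(f1)
  expect_equal(back$x, ctr$x)
  write_tessellation_csv(tt, f2)
  summ <- read.csv(f2)
  expect_equal(summ$V, tt$cells$V)
  expect_equal(summ$is_boundary, tt$cells$boundary)
})
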