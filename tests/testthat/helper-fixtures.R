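# shared fixtures, built in code

ref_force <- function() exp_force() # mu = 50, s = 1, c = 10, r_A = 1.5

# perturbed hexagonal configuration on a square domain, in general
# position so the vertex mesh is 3-valent
perturbed_hex <- function(h = 1, L = 10, sd = 0.02, seed = 3) {
  dom <- sim_domain(c(0, 0), c(L, L))
  ic <- ic_hex_2d(dom, h)
  withr::with_seed(seed, {
    ic$x <- pmin(pmax(ic$x + rnorm(nrow(ic), 0, sd), 0.05), L - 0.05)
    ic$y <- pmin(pmax(ic$y + rnorm(nrow(ic), 0, sd), 0.05), L - 0.05)
  })
  list(centers = ic, domain = dom)
}

# small random point set strictly inside a rectangle
random_centers <- function(n, dom, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = runif(n, dom$lower[1] + 0.02, dom$upper[1] - 0.02),
      y = runif(n, dom$lower[2] + 0.02, dom$upper[2] - 0.02))
  })
}

# indices of cells far enough from the walls to be unaffected by clipping
deep_cells <- function(tess, margin) {
  which(tess$cells$x > tess$domain$lower[1] + margin &
          tess$cells$x < tess$domain$upper[1] - margin &
          tess$cells$y > tess$domain$lower[2] + margin &
          tess$cells$y < tess$domain$upper[2] - margin)
}

# interior mesh vertices whose three incident cells all have the ideal
# hexagonal area (deep inside an exact lattice)
deep_hex_vertices <- function(mesh, stats, h = 1) {
  ideal <- sqrt(3) / 2 * h^2
  int_v <- which(!mesh$vertices$boundary)
  int_v[vapply(int_v, function(a) {
    ks <- mesh$incident_cells[[a]]
    length(ks) == 3 && all(abs(stats$V[ks] - ideal) < 1e-9)
  }, logical(1))]
}

# pressure as a function of density (for numeric differentiation)
element_p <- function(law, rho) law_pressure(law, 1 / rho)

# total variation in excess of a single smooth dip/peak: ~0 for a clean
# monotone or single-extremum profile, > 0 for added oscillations
oscillation_excess <- function(z) {
  sum(abs(diff(z))) - 2 * (max(z) - min(z))
}
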