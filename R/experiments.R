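#' Smoothly perturbed 1D initial cell positions
#'
#' Places `N` cell centers in a 1D domain so that the per-cell density
#' from [tessellate_1d()] tracks a smooth target profile
#' `rho(x) = base_density + amplitude cos^2(pi (x - center)/(2 width))`
#' inside the bump and `base_density` outside (negative `amplitude`
#' carves a depletion).  Centers sit at the mass quantiles
#' `F(x_i) = (i - 1/2) M/N` of the profile, found by monotone inversion
#' refined with Newton steps; when the profile mass `M` equals `N` (as
#' in the presets) the realized per-cell density matches the profile up
#' to discretization.  The two extreme cells are flagged frozen.
#'
#' @param N number of cells (>= 2).
#' @param domain a 1D [sim_domain()].
#' @param base_density equilibrium density away from the bump.
#' @param center,width,amplitude bump location, half-width and height;
#'   `amplitude = 0` gives equispaced centers.
#' @return tibble with columns `x` and `frozen`.
#' @examples
#' ic <- ic_profile_1d(40, sim_domain(0, 37), 1, 18.5, 5, 0.6)
#' @export
ic_profile_1d <- function(N, domain, base_density = 1, center = NA,
                          width = 0, amplitude = 0) {
  if (domain$d != 1) abort("`domain` must be one-dimensional.")
  if (N < 2) abort("`N` must be at least 2.")
  lo <- domain$lower; hi <- domain$upper
  if (is.na(center)) center <- (lo + hi) / 2
  if (amplitude != 0 && width <= 0) abort("`width` must be positive.")
  if (base_density + min(0, amplitude) <= 0)
    abort("profile is non-positive somewhere: cell spacings would be negative.")
  prof <- function(x) {
    u <- x - center
    b <- ifelse(abs(u) < width & width > 0,
                amplitude * cos(pi * u / (2 * width))^2, 0)
    base_density + b
  }
  cumb <- function(x) { # integral of the bump from lo to x
    if (width <= 0) return(numeric(length(x)))
    u <- pmin(pmax(x - center, -width), width)
    amplitude * (u / 2 + width / (2 * pi) * sin(pi * u / width) + width / 2)
  }
  F_ <- function(x) base_density * (x - lo) + cumb(x)
  M <- F_(hi)
  targets <- (seq_len(N) - 0.5) * M / N
  xg <- seq(lo, hi, length.out = 4001)
  x <- approx(F_(xg), xg, xout = targets, ties = "ordered")$y
  for (k in 1:3) x <- x - (F_(x) - targets) / prof(x) # Newton polish
  x <- pmin(pmax(x, lo + 1e-9 * (hi - lo)), hi - 1e-9 * (hi - lo))
  if (any(diff(x) <= 0)) abort("profile forces non-increasing centers.")
  tibble(x = x, frozen = seq_len(N) %in% c(1L, N))
}

#' Hexagonal 2D initial cell positions with a radial central disturbance
#'
#' Fills the domain with a triangular lattice of spacing `h` (uniform
#' density `2/(sqrt(3) h^2)` away from the boundary), then compresses
#' cells radially toward `center` inside `radius` with the smooth map
#' `m(r) = r (1 - a cos^2(pi r/(2 radius)))`, `a = 1 - 1/sqrt(factor)`, so
#' that the central density is multiplied by `factor`; a shallow
#' compensating depletion appears near the disturbance edge.  Identity
#' map when `factor = 1`.
#'
#' @param domain a 2D [sim_domain()].
#' @param h lattice spacing (nearest-neighbor distance).
#' @param center disturbance center, default the domain center.
#' @param radius disturbance radius (0 disables the disturbance).
#' @param factor central density multiplication factor (>= 1).
#' @return tibble with columns `x`, `y`.
#' @export
ic_hex_2d <- function(domain, h, center = NULL, radius = 0, factor = 1) {
  if (domain$d != 2) abort("`domain` must be two-dimensional.")
  if (h <= 0) abort("`h` must be positive.")
  if (factor < 1) abort("`factor` must be >= 1.")
  if (is.null(center)) center <- (domain$lower + domain$upper) / 2
  lo <- domain$lower; hi <- domain$upper
  dy <- h * sqrt(3) / 2
  ys <- seq(lo[2] + h / 2, hi[2] - h / 2 + 1e-12, by = dy)
  pts <- dplyr::bind_rows(lapply(seq_along(ys), function(r) {
    x0 <- lo[1] + h / 2 + (r %% 2) * h / 2
    xs <- seq(x0, hi[1] - h / 2 + 1e-12, by = h)
    tibble(x = xs, y = ys[r])
  }))
  if (radius > 0 && factor > 1) {
    a <- 1 - 1 / sqrt(factor)
    rx <- pts$x - center[1]; ry <- pts$y - center[2]
    r <- sqrt(rx^2 + ry^2)
    inside <- r < radius & r > 0
    shrink <- 1 - a * cos(pi * r[inside] / (2 * radius))^2
    pts$x[inside] <- center[1] + rx[inside] * shrink
    pts$y[inside] <- center[2] + ry[inside] * shrink
  }
  pr <- cg_pairs_within(pts$x, pts$y, 1e-3 * h)
  if (length(pr$i))
    abort("disturbance drove cell centers into collision; reduce `factor`.")
  pts
}

#' Interpolate per-cell density samples onto a finite-volume grid
#'
#' 1D: linear interpolation between sample positions.  2D:
#' piecewise-linear (barycentric) interpolation on the Delaunay
#' triangulation of the sample positions, recovered from the dual of
#' their Voronoi tessellation; grid centers outside the triangulation
#' fall back to the nearest sample.
#'
#' @param samples tibble with `x[, y]` and `rho` (e.g. from
#'   [density_field()]).
#' @param grid an [build_grid()] grid; its domain should be covered by
#'   the samples.
#' @return a `grid_field` at `t = 0`.
#' @export
micro_to_grid <- function(samples, grid) {
  if (nrow(samples) == 0) abort("`samples` is empty.")
  ctr <- grid$centers
  if (grid$d == 1) {
    o <- order(samples$x)
    rho <- approx(samples$x[o], samples$rho[o], xout = ctr$x, rule = 2,
                  ties = "ordered")$y
    return(grid_field(grid, rho))
  }
  tri <- delaunay_triangles(samples$x, samples$y)
  rho <- barycentric_interp(samples$x, samples$y, samples$rho, tri,
                            ctr$x, ctr$y)
  grid_field(grid, rho)
}

# Delaunay triangles of scattered points: tessellate on a slightly
# expanded bounding box; each interior Voronoi vertex with exactly three
# incident cells is the circumcenter of a Delaunay triangle.
delaunay_triangles <- function(x, y) {
  pad <- 0.05 * max(diff(range(x)), diff(range(y)))
  dom <- sim_domain(c(min(x) - pad, min(y) - pad),
                    c(max(x) + pad, max(y) + pad))
  tess <- tessellate_2d(tibble(x = x, y = y), dom, mesh = TRUE)
  inc <- tess$mesh$incident_cells
  tri <- do.call(rbind, inc[lengths(inc) == 3])
  unique(t(apply(tri, 1, sort)))
}

barycentric_interp <- function(px, py, pz, tri, qx, qy) {
  x1 <- px[tri[, 1]]; y1 <- py[tri[, 1]]
  x2 <- px[tri[, 2]]; y2 <- py[tri[, 2]]
  x3 <- px[tri[, 3]]; y3 <- py[tri[, 3]]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  bx0 <- pmin(x1, x2, x3); bx1 <- pmax(x1, x2, x3)
  by0 <- pmin(y1, y2, y3); by1 <- pmax(y1, y2, y3)
  tol <- 1e-9
  out <- numeric(length(qx))
  for (q in seq_along(qx)) {
    cand <- which(qx[q] >= bx0 - tol & qx[q] <= bx1 + tol &
                    qy[q] >= by0 - tol & qy[q] <= by1 + tol & abs(det) > 0)
    hit <- FALSE
    for (tr in cand) {
      l1 <- ((y2[tr] - y3[tr]) * (qx[q] - x3[tr]) +
               (x3[tr] - x2[tr]) * (qy[q] - y3[tr])) / det[tr]
      l2 <- ((y3[tr] - y1[tr]) * (qx[q] - x3[tr]) +
               (x1[tr] - x3[tr]) * (qy[q] - y3[tr])) / det[tr]
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        out[q] <- l1 * pz[tri[tr, 1]] + l2 * pz[tri[tr, 2]] +
          l3 * pz[tri[tr, 3]]
        hit <- TRUE
        break
      }
    }
    if (!hit) out[q] <- pz[which.min((px - qx[q])^2 + (py - qy[q])^2)]
  }
  out
}

#' Extract a constant-y line profile from a 2D field
#'
#' Returns the row of element-center densities nearest the requested
#' `y`, with their x coordinates -- the comparison line of the 2D
#' experiments.
#'
#' @param field a 2D `grid_field`.
#' @param y coordinate inside the grid domain.
#' @return tibble with columns `x`, `rho`.
#' @export
line_profile <- function(field, y) {
  g <- field$grid
  if (g$d != 2) abort("`field` must be two-dimensional.")
  if (y < g$domain$lower[2] || y > g$domain$upper[2])
    abort("`y` is outside the grid domain.")
  ys <- unique(g$centers$y)
  yj <- ys[which.min(abs(ys - y))]
  td <- tidy(field)
  sel <- td[td$y == yj, ]
  tibble(x = sel$x, rho = sel$rho)
}

#' Compare micro density samples with a macro field
#'
#' Interpolates the micro samples onto the macro element centers inside
#' `region` and reports the L-infinity and L2 differences plus the
#' total-mass difference over the region.
#'
#' @param micro tibble of per-cell samples (`x[, y]`, `rho`).
#' @param field a `grid_field`.
#' @param region optional [sim_domain()] restricting the comparison;
#'   default the whole grid domain.
#' @return one-row tibble with `linf`, `l2`, `mass_diff`, `n_elements`.
#' @export
compare_density <- function(micro, field, region = NULL) {
  g <- field$grid
  if (is.null(region)) region <- g$domain
  keep <- g$centers$x >= region$lower[1] & g$centers$x <= region$upper[1]
  if (g$d == 2)
    keep <- keep & g$centers$y >= region$lower[2] &
      g$centers$y <= region$upper[2]
  if (!any(keep)) abort("`region` does not overlap the grid.")
  mi <- micro_to_grid(micro, g)$rho[keep]
  ma <- field$rho[keep]
  diffs <- mi - ma
  tibble(linf = max(abs(diffs)),
         l2 = sqrt(g$omega * sum(diffs^2)),
         mass_diff = g$omega * sum(diffs),
         n_elements = sum(keep))
}
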