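#' Weliky-Oster vertex force parameters
#'
#' @param sigma area force coefficient (the `1/V` term).
#' @param kappa perimeter force coefficient.
#' @param eta viscosity scaling.
#' @return A `wo_params` object.
#' @export
wo_params <- function(sigma, kappa = 0, eta = 1) {
  if (sigma < 0 || kappa < 0) abort("`sigma` and `kappa` must be >= 0.")
  if (sigma == 0 && kappa == 0) abort("`sigma` and `kappa` cannot both be 0.")
  if (eta <= 0) abort("`eta` must be positive.")
  structure(list(sigma = sigma, kappa = kappa, eta = eta),
            class = "wo_params")
}

#' Nagai-Honda vertex force parameters
#'
#' Gradient-of-energy vertex force with deformation coefficient
#' `lambda`, membrane surface coefficient `beta`, per-cell adhesion
#' coefficient `gamma`, and ideal area `V0` and perimeter `a0` (scalars
#' or per-cell vectors).
#'
#' @param lambda deformation energy coefficient (>= 0).
#' @param beta membrane surface energy coefficient (>= 0).
#' @param gamma cell-cell adhesion energy coefficient.
#' @param V0 ideal cell area(s), positive.
#' @param a0 ideal cell perimeter(s), positive.
#' @param eta viscosity scaling.
#' @return An `nh_params` object.
#' @export
nh_params <- function(lambda, beta, gamma = 0, V0, a0, eta = 1) {
  if (lambda < 0 || beta < 0) abort("`lambda` and `beta` must be >= 0.")
  if (any(V0 <= 0) || any(a0 <= 0)) abort("`V0` and `a0` must be positive.")
  if (eta <= 0) abort("`eta` must be positive.")
  structure(list(lambda = lambda, beta = beta, gamma = gamma,
                 V0 = V0, a0 = a0, eta = eta),
            class = "nh_params")
}

#' Weliky-Oster force function
#'
#' The scalar force magnitude `f(V, a, b) = sigma/V + kappa (a + b)`
#' assigned to a vertex edge, where `V` is the area of the cell opposite
#' the edge and `a`, `b` are the perimeters of the two cells flanking it.
#' It splits additively as `f = f_V(V) + f_a(a) + f_a(b)` with
#' `f_V = sigma/V` and `f_a = kappa a`, which is what the coarse-graining
#' uses.
#'
#' @param V opposite-cell area(s), positive.
#' @param a,b flanking-cell perimeters, non-negative.
#' @param params a [wo_params()].
#' @return numeric force magnitude(s).
#' @export
wo_force_function <- function(V, a, b, params) {
  if (any(V <= 0)) abort("`V` must be positive.")
  if (any(a < 0) || any(b < 0)) abort("perimeters must be non-negative.")
  params$sigma / V + params$kappa * (a + b)
}

#' Areas and perimeters of the cells of a vertex mesh
#'
#' @param mesh a `vertex_mesh`.
#' @return tibble with columns `cell`, `V` (shoelace area, orientation
#'   corrected) and `a` (perimeter).
#' @export
mesh_cell_stats <- function(mesh) {
  vx <- mesh$vertices$x; vy <- mesh$vertices$y
  st <- vapply(mesh$cells, function(r) {
    x <- vx[r]; y <- vy[r]
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    c(abs(sum(x * y2 - x2 * y)) / 2, sum(sqrt((x2 - x)^2 + (y2 - y)^2)))
  }, numeric(2))
  tibble(cell = seq_along(mesh$cells), V = st[1, ], a = st[2, ])
}

# For an interior 3-valent vertex alpha: its three outgoing edges, the
# cell opposite each edge, and the two cells flanking it.  The edge
# toward beta is shared by two of the three cells incident at alpha (the
# flanking ones); the third cell is the opposite one.
vertex_edge_pairing <- function(mesh, alpha) {
  if (mesh$degenerate)
    abort("degenerate vertex mesh (cocircular centers); vertex forces need 3 cells per vertex.")
  if (mesh$vertices$boundary[alpha])
    abort(sprintf("vertex %d is a boundary vertex; boundary policy is handled by the integrator.", alpha))
  nbrs <- mesh$adjacency[[alpha]]
  cells <- mesh$incident_cells[[alpha]]
  if (length(nbrs) != 3 || length(cells) != 3)
    abort(sprintf("vertex %d is not 3-valent.", alpha))
  flank <- lapply(nbrs, function(b) {
    cells[vapply(cells, function(k) {
      r <- mesh$cells[[k]]
      any(r == alpha) && any(r == b) &&
        abs(diff(c(which(r == alpha)[1], which(r == b)[1]))) %in%
          c(1, length(r) - 1)
    }, logical(1))]
  })
  opp <- vapply(seq_along(nbrs), function(e) setdiff(cells, flank[[e]])[1],
                integer(1))
  list(to = nbrs, opp = opp, flank = flank)
}

#' Vertex velocities of the 2D vertex-based models
#'
#' `wo_vertex_velocity()` evaluates the Weliky-Oster velocity of an
#' interior vertex: each of its three outgoing edge directions is
#' weighted by `f(V, a, b)` with `V` the area of the cell opposite that
#' edge and `a`, `b` the perimeters of the two flanking cells.
#' `nh_vertex_velocity()` evaluates the Nagai-Honda velocity: each
#' incident cell `k` contributes
#' `-lambda (V_k - V0_k) r_ab rhat_ab + (2 beta (a_k - a0_k) + gamma_k)
#' (rhat_ac + rhat_ad)` where the edge toward `b` is the one opposite
#' cell `k` and `c`, `d` are the other two neighbors.  Both use the same
#' edge--cell pairing helper.
#'
#' @param mesh a `vertex_mesh`.
#' @param alpha interior vertex index (3 incident cells).
#' @param params [wo_params()] or [nh_params()].
#' @param stats optional precomputed [mesh_cell_stats()].
#' @return length-2 numeric velocity vector.
#' @export
wo_vertex_velocity <- function(mesh, alpha, params, stats = NULL) {
  if (is.null(stats)) stats <- mesh_cell_stats(mesh)
  pr <- vertex_edge_pairing(mesh, alpha)
  p0 <- c(mesh$vertices$x[alpha], mesh$vertices$y[alpha])
  v <- c(0, 0)
  for (e in 1:3) {
    dir <- c(mesh$vertices$x[pr$to[e]], mesh$vertices$y[pr$to[e]]) - p0
    dir <- dir / sqrt(sum(dir^2))
    f <- wo_force_function(stats$V[pr$opp[e]],
                           stats$a[pr$flank[[e]][1]],
                           stats$a[pr$flank[[e]][2]], params)
    v <- v + f * dir
  }
  v / params$eta
}

#' @rdname wo_vertex_velocity
#' @export
nh_vertex_velocity <- function(mesh, alpha, params, stats = NULL) {
  if (is.null(stats)) stats <- mesh_cell_stats(mesh)
  pr <- vertex_edge_pairing(mesh, alpha)
  p0 <- c(mesh$vertices$x[alpha], mesh$vertices$y[alpha])
  per_cell <- function(p, k) if (length(p) > 1) p[k] else p
  v <- c(0, 0)
  for (e in 1:3) {
    k <- pr$opp[e]
    dvec <- c(mesh$vertices$x[pr$to[e]], mesh$vertices$y[pr$to[e]]) - p0
    r_ab <- sqrt(sum(dvec^2))
    rhat <- dvec / r_ab
    v <- v - params$lambda * (stats$V[k] - per_cell(params$V0, k)) *
      r_ab * rhat
    # the other two edges bound cell k at alpha
    others <- setdiff(1:3, e)
    wsum <- c(0, 0)
    for (o in others) {
      od <- c(mesh$vertices$x[pr$to[o]], mesh$vertices$y[pr$to[o]]) - p0
      wsum <- wsum + od / sqrt(sum(od^2))
    }
    v <- v + (2 * params$beta * (stats$a[k] - per_cell(params$a0, k)) +
                per_cell(params$gamma, k)) * wsum
  }
  v / params$eta
}

#' Parameter correspondences between the force models
#'
#' `match_wo_to_cbm()` returns the Weliky-Oster parameters whose 1D
#' small-perturbation response equals that of a center-based law around
#' its rest distance: `sigma = g'(s) V0^2`, `kappa = 0` (for the
#' exponential law `g'(s) = mu`).  `match_nh_to_wo()` returns the
#' Nagai-Honda parameters that agree with a Weliky-Oster model to first
#' order around the ideal configuration:
#' `lambda = sigma/(r_edge V0^2)`, `beta = kappa/2`, `gamma = 0`.
#'
#' @param law a `force_law`.
#' @param V0 equilibrium cell volume (length in 1D, area in 2D).
#' @param params a [wo_params()].
#' @param r_edge equilibrium edge length between adjacent vertices.
#' @param a0 ideal perimeter passed through to the result.
#' @return [wo_params()] or [nh_params()].
#' @export
match_wo_to_cbm <- function(law, V0) {
  if (V0 <= 0) abort("`V0` must be positive.")
  wo_params(sigma = force_gprime(law, force_rest(law)) * V0^2, kappa = 0,
            eta = law$eta)
}

#' @rdname match_wo_to_cbm
#' @export
match_nh_to_wo <- function(params, V0, r_edge, a0 = 6 * r_edge) {
  if (V0 <= 0 || r_edge <= 0) abort("`V0` and `r_edge` must be positive.")
  nh_params(lambda = params$sigma / (r_edge * V0^2),
            beta = params$kappa / 2, gamma = 0,
            V0 = V0, a0 = a0, eta = params$eta)
}

#' Vertex force function induced by a center-based law
#'
#' A center-based force can drive a 2D vertex model through the shared
#' macroscopic pressure: `f(V) = -(J xi_2(J)/2)^2 g(2 xi_2(J) sqrt(V))`.
#' Plugged into the Weliky-Oster area slot (`f_a = 0`), the resulting
#' macroscopic pressure equals the center-based pressure law exactly.
#'
#' @param V cell area(s), positive.
#' @param law a `force_law`.
#' @param J neighbor count of the regular-polygon idealization.
#' @param xi2 the shape factor; defaults to `xi_factor(2, J)`.
#' @return numeric force magnitude(s).
#' @export
f_from_cbm <- function(V, law, J = 6, xi2 = xi_factor(2, J)) {
  if (any(V <= 0)) abort("`V` must be positive.")
  -(J * xi2 / 2)^2 * force_g(law, 2 * xi2 * sqrt(V))
}
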