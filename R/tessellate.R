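#' Voronoi tessellation of cell centers in 1D
#'
#' Each cell occupies the interval between the midpoints to its left and
#' right neighbors; the first and last cells are clipped at the domain
#' bounds, so the cells partition the domain exactly.  In 1D the
#' interface "measure" between adjacent cells is 1 by convention and every
#' interior cell has the two adjacent cells as neighbors.
#'
#' @param centers data frame (or matrix) with a column `x`; original row
#'   order is preserved in the output and recorded in `$order`.
#' @param domain a [sim_domain()] with `d = 1`; all centers must lie
#'   strictly inside it.
#' @return A `tessellation` object: `$cells` tibble
#'   (`cell, x, V, rho, a, r_in, n_neighbors, boundary`), `$neighbors`
#'   tibble (`i, j, a_ij, r_ij, nx`), `$order` (original indices sorted
#'   by position), `$d`, `$domain`.
#' @examples
#' tess <- tessellate_1d(data.frame(x = c(0.5, 1.5, 2.5)), sim_domain(0, 3))
#' tess$cells$V
#' @export
tessellate_1d <- function(centers, domain) {
  if (domain$d != 1) abort("`domain` must be one-dimensional.")
  m <- coord_matrix(centers, 1)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 cell centers.")
  check_inside(m, domain)
  x <- m[, 1]
  ord <- order(x)
  xs <- x[ord]
  tol <- 1e-12 * (domain$upper - domain$lower)
  dup <- which(diff(xs) < tol)
  if (length(dup))
    abort(sprintf("duplicate cell centers at indices %d and %d.",
                  ord[dup[1]], ord[dup[1] + 1]))
  # cell boundaries: domain ends and midpoints between sorted neighbors
  b <- c(domain$lower, (xs[-n] + xs[-1]) / 2, domain$upper)
  V_sorted <- diff(b)
  V <- numeric(n); V[ord] <- V_sorted
  r_in <- numeric(n)
  r_in[ord] <- pmin(xs - b[-(n + 1)], b[-1] - xs)
  boundary <- logical(n); boundary[ord[c(1, n)]] <- TRUE

  # adjacency in original indexing, both directions
  i_s <- ord[-n]; j_s <- ord[-1]
  nbr <- tibble(
    i = c(i_s, j_s), j = c(j_s, i_s),
    a_ij = 1,
    r_ij = rep(diff(xs), 2),
    nx = rep(c(1, -1), each = n - 1))
  n_nbr <- tabulate(nbr$i, nbins = n)

  cells <- tibble(
    cell = seq_len(n), x = x, V = V, rho = 1 / V,
    a = 2, r_in = r_in, n_neighbors = n_nbr, boundary = boundary)
  structure(
    list(d = 1L, domain = domain, cells = cells, neighbors = nbr,
         order = ord, polygons = NULL, mesh = NULL),
    class = "tessellation")
}

#' Bounded Voronoi tessellation of cell centers in 2D
#'
#' Computes the Voronoi region of every center clipped to the rectangular
#' domain (equivalent to closing unbounded regions with centers mirrored
#' across each face), so that the regions partition the domain exactly.
#' Returns per-cell areas, perimeters, shared-edge lengths, neighbor sets
#' and edge normals, the cell polygons, and (optionally) the dual vertex
#' mesh used by the vertex-based model.
#'
#' @param centers data frame (or matrix) with columns `x`, `y`.
#' @param domain a [sim_domain()] with `d = 2`.
#' @param mesh build the vertex mesh (`$mesh`)?  Set `FALSE` in tight
#'   simulation loops where only areas and adjacency are needed.
#' @param polygons return cell polygons?  Implied by `mesh = TRUE`.
#' @return A `tessellation` object as in [tessellate_1d()], with
#'   `$neighbors` columns (`i, j, a_ij, r_ij, nx, ny`), `$polygons` (list
#'   of vertex matrices) and `$mesh` (a `vertex_mesh`, see
#'   [build_vertex_mesh()]).
#' @export
tessellate_2d <- function(centers, domain, mesh = TRUE, polygons = TRUE) {
  if (domain$d != 2) abort("`domain` must be two-dimensional.")
  m <- coord_matrix(centers, 2)
  n <- nrow(m)
  if (n < 3) abort("need at least 3 cell centers in 2D.")
  check_inside(m, domain)
  scale <- max(domain$upper - domain$lower)
  # all-collinear rejection
  cm <- sweep(m, 2, colMeans(m))
  if (svd(cm, nu = 0, nv = 0)$d[2] < 1e-12 * scale * sqrt(n))
    abort("cell centers are collinear; 2D tessellation needs full rank.")

  want_poly <- polygons || mesh
  vor <- cg_voronoi_rect(m[, 1], m[, 2],
                         domain$lower[1], domain$upper[1],
                         domain$lower[2], domain$upper[2], want_poly)

  # symmetrize shared-edge lengths (computed independently per cell)
  key_lo <- pmin(vor$nbr_i, vor$nbr_j)
  key_hi <- pmax(vor$nbr_i, vor$nbr_j)
  key <- paste(key_lo, key_hi)
  a_sym <- tapply(vor$nbr_len, key, mean)
  pair_key <- names(a_sym)
  pk <- do.call(rbind, strsplit(pair_key, " "))
  pi_ <- as.integer(pk[, 1]); pj_ <- as.integer(pk[, 2])
  i_all <- c(pi_, pj_); j_all <- c(pj_, pi_)
  dx <- m[j_all, 1] - m[i_all, 1]
  dy <- m[j_all, 2] - m[i_all, 2]
  r_ij <- sqrt(dx^2 + dy^2)
  nbr <- tibble(
    i = i_all, j = j_all, a_ij = rep(as.numeric(a_sym), 2),
    r_ij = r_ij, nx = dx / r_ij, ny = dy / r_ij)
  nbr <- nbr[order(nbr$i, nbr$j), ]
  n_nbr <- tabulate(nbr$i, nbins = n)

  # inradius: half the distance to the nearest Voronoi neighbor, or the
  # distance to the nearest domain face for boundary cells
  r_half <- tapply(nbr$r_ij / 2, factor(nbr$i, levels = seq_len(n)),
                   min, default = Inf)
  face_d <- pmin(m[, 1] - domain$lower[1], domain$upper[1] - m[, 1],
                 m[, 2] - domain$lower[2], domain$upper[2] - m[, 2])
  r_in <- ifelse(vor$boundary, pmin(r_half, face_d), r_half)

  cells <- tibble(
    cell = seq_len(n), x = m[, 1], y = m[, 2],
    V = vor$area, rho = 1 / vor$area, a = vor$perim, r_in = as.numeric(r_in),
    n_neighbors = n_nbr, boundary = vor$boundary)

  tess <- structure(
    list(d = 2L, domain = domain, cells = cells, neighbors = nbr,
         order = seq_len(n),
         polygons = if (want_poly) vor$polys else NULL,
         edge_labels = if (want_poly) vor$edge_labs else NULL,
         mesh = NULL),
    class = "tessellation")
  if (mesh) tess$mesh <- build_vertex_mesh(tess)
  tess
}

#' @export
print.tessellation <- function(x, ...) {
  cat("<tessellation> d =", x$d, "with", nrow(x$cells), "cells;",
      sum(x$cells$boundary), "touch the boundary\n")
  invisible(x)
}

#' @rdname tessellate_1d
#' @param x a `tessellation`.
#' @param ... unused.
#' @export
tidy.tessellation <- function(x, ...) x$cells

#' Extract per-cell density samples from a tessellation
#'
#' The cell density is the reciprocal cell volume, `rho_i = 1/V_i`,
#' attributed to the cell center.
#'
#' @param tess a `tessellation`.
#' @return tibble with the center coordinates, `V` and `rho`.
#' @export
cell_density <- function(tess) {
  cols <- intersect(c("cell", "x", "y", "V", "rho", "boundary"),
                    names(tess$cells))
  if (any(tess$cells$V <= 0)) abort("non-positive cell volume.")
  tess$cells[cols]
}

#' Dual vertex mesh of a 2D tessellation
#'
#' Collects the Voronoi vertices of all cell polygons, identifies
#' coincident vertices across cells (single-linkage clustering at
#' tolerance `1e-9` of the domain scale), and assembles the
#' vertex--vertex adjacency and vertex--cell incidence used by the
#' vertex-based model.  Interior vertices of centers in general position
#' have exactly 3 incident cells and 3 adjacent vertices; meshes where an
#' interior vertex has more incident cells (cocircular centers) are
#' flagged `degenerate` and rejected by the vertex force routines.
#'
#' @param tess a 2D `tessellation` with polygons.
#' @return A `vertex_mesh`: `$vertices` tibble (`vertex, x, y, boundary`),
#'   `$cells` list of ordered vertex-id rings, `$adjacency` and
#'   `$incident_cells` lists indexed by vertex, `$degenerate` flag.
#' @export
build_vertex_mesh <- function(tess) {
  if (tess$d != 2 || is.null(tess$polygons))
    abort("a 2D tessellation with polygons is required.")
  scale <- max(tess$domain$upper - tess$domain$lower)
  tol <- 1e-9 * scale

  vx <- unlist(lapply(tess$polygons, function(p) p[, 1]))
  vy <- unlist(lapply(tess$polygons, function(p) p[, 2]))
  owner <- rep(seq_along(tess$polygons),
               vapply(tess$polygons, nrow, integer(1)))
  id <- cluster_points(vx, vy, tol)
  nv <- max(id)
  ux <- as.numeric(tapply(vx, id, mean))
  uy <- as.numeric(tapply(vy, id, mean))

  # polygons as vertex-id rings (drop consecutive duplicates after merging)
  off <- c(0L, cumsum(vapply(tess$polygons, nrow, integer(1))))
  rings <- lapply(seq_along(tess$polygons), function(k) {
    ids <- id[(off[k] + 1L):off[k + 1L]]
    keep <- ids != c(ids[-1], ids[1])
    ids[keep]
  })

  inc <- vector("list", nv)
  for (k in seq_along(rings))
    for (v in rings[[k]]) inc[[v]] <- c(inc[[v]], k)
  inc <- lapply(inc, unique)

  e1 <- unlist(lapply(rings, function(r) r))
  e2 <- unlist(lapply(rings, function(r) c(r[-1], r[1])))
  ekey <- paste(pmin(e1, e2), pmax(e1, e2))
  keep <- !duplicated(ekey)
  e1u <- e1[keep]; e2u <- e2[keep]
  adj <- vector("list", nv)
  for (e in seq_along(e1u)) {
    adj[[e1u[e]]] <- c(adj[[e1u[e]]], e2u[e])
    adj[[e2u[e]]] <- c(adj[[e2u[e]]], e1u[e])
  }

  on_rect <- abs(ux - tess$domain$lower[1]) < tol |
    abs(ux - tess$domain$upper[1]) < tol |
    abs(uy - tess$domain$lower[2]) < tol |
    abs(uy - tess$domain$upper[2]) < tol
  n_inc <- lengths(inc)
  boundary <- on_rect | n_inc < 3
  degenerate <- any(!on_rect & n_inc > 3)

  structure(
    list(vertices = tibble(vertex = seq_len(nv), x = ux, y = uy,
                           boundary = boundary),
         cells = rings, adjacency = adj, incident_cells = inc,
         degenerate = degenerate, domain = tess$domain),
    class = "vertex_mesh")
}

#' @export
print.vertex_mesh <- function(x, ...) {
  cat("<vertex_mesh>", nrow(x$vertices), "vertices,", length(x$cells),
      "cells", if (x$degenerate) "(degenerate incidence)" else "", "\n")
  invisible(x)
}

# single-linkage clustering of points at tolerance tol (union-find over a
# bucket grid); returns cluster ids 1..k in order of first appearance
cluster_points <- function(x, y, tol) {
  n <- length(x)
  gx <- floor(x / tol); gy <- floor(y / tol)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  bucket_of <- function(a, b) buckets[[paste(a, b)]]
  for (b in names(buckets)) {
    ab <- as.numeric(strsplit(b, " ")[[1]])
    cand <- unlist(lapply(c(-1, 0, 1), function(dx)
      lapply(c(-1, 0, 1), function(dy) bucket_of(ab[1] + dx, ab[2] + dy))),
      use.names = FALSE)
    pts <- buckets[[b]]
    for (p in pts) for (q in cand) {
      if (q <= p) next
      if (abs(x[p] - x[q]) < tol && abs(y[p] - y[q]) < tol) {
        rp <- find(p); rq <- find(q)
        if (rp != rq) parent[max(rp, rq)] <- min(rp, rq)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
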