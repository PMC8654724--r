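#' Regular-shape geometry factor xi_d(J)
#'
#' For a cell idealized as a regular interval (d = 1), polygon (d = 2,
#' J edges) or polyhedron (d = 3, J faces), the inradius r, volume V,
#' interface measure and perimeter are tied together by a single
#' dimensionless factor `xi_d(J)` defined through `r_i = xi_d(J) V^(1/d)`.
#' It is the bridge between the force laws, which see distances and
#' perimeters, and the macroscale, which only sees the cell volume
#' `V = 1/rho`.
#'
#' Closed forms: `xi_1 = 1/2`; `xi_2(J) = (J tan(pi/J))^(-1/2)` with the
#' circle limit `1/sqrt(pi)`; `xi_3(J)` from the Platonic solids with
#' J = 4, 6, 8, 12 faces and the sphere limit `(3/(4 pi))^(1/3)`.  For
#' d = 3 and other J no regular polyhedron exists; a value is produced by
#' piecewise-linear interpolation in 1/J through the Platonic values and
#' the sphere limit (or supply `xi_override`).
#'
#' @param d dimension, 1, 2 or 3.
#' @param J number of neighbors (edges/faces); `Inf` for the circle or
#'   sphere limit.  Ignored for d = 1.  May be a vector.
#' @param xi_override optional numeric: use this value verbatim for a
#'   (d = 3, J) pair without a Platonic closed form.
#' @return numeric vector of xi values.
#' @examples
#' xi_factor(2, 6)      # hexagon, 0.5373
#' xi_factor(2, Inf)    # circle limit 1/sqrt(pi)
#' xi_factor(3, 12)     # dodecahedron, 0.5648
#' @export
xi_factor <- function(d, J = NULL, xi_override = NULL) {
  if (!length(d) == 1 || !d %in% 1:3) abort("`d` must be 1, 2 or 3.")
  if (d == 1) return(0.5)
  if (is.null(J)) abort("`J` is required for d = 2 or 3.")
  if (!is.null(xi_override)) {
    if (d != 3) abort("`xi_override` only applies to d = 3.")
    return(rep_len(as.numeric(xi_override), length(J)))
  }
  if (d == 2) {
    if (any(is.finite(J) & (J < 3 | J != round(J))))
      abort("for d = 2, `J` must be an integer >= 3 or Inf.")
    return(ifelse(is.infinite(J), 1 / sqrt(pi), 1 / sqrt(J * tan(pi / J))))
  }
  # d == 3: Platonic closed forms
  xi3 <- function(j) {
    if (is.infinite(j)) return((3 / (4 * pi))^(1 / 3))
    switch(as.character(j),
      "4"  = 1 / (2 * 3^(1 / 6)),
      "6"  = 0.5,
      "8"  = 1 / (2^(2 / 3) * 3^(1 / 6)),
      "12" = {
        s5 <- sqrt(5)
        4^(1 / 3) * sqrt(250 + 110 * s5) / (20 * (15 + 7 * s5)^(1 / 3))
      },
      xi3_interp(j)
    )
  }
  vapply(J, xi3, numeric(1))
}

# piecewise-linear in 1/J through the Platonic values and the sphere limit
xi3_interp <- function(j) {
  if (j < 4) abort("for d = 3, `J` must be >= 4 (or Inf).")
  knots_J <- c(4, 6, 8, 12, Inf)
  knots_x <- 1 / knots_J
  knots_v <- c(
    1 / (2 * 3^(1 / 6)), 0.5, 1 / (2^(2 / 3) * 3^(1 / 6)),
    4^(1 / 3) * sqrt(250 + 110 * sqrt(5)) / (20 * (15 + 7 * sqrt(5))^(1 / 3)),
    (3 / (4 * pi))^(1 / 3))
  approx(knots_x, knots_v, xout = 1 / j, rule = 2)$y
}

#' Regular-shape relations between volume, inradius, interface and perimeter
#'
#' Evaluates, for a regular cell of volume `V` in dimension `d` with `J`
#' neighbors, the inradius `r_i = xi_d(J) V^(1/d)`, the volume-to-interface
#' ratio `V/a_ij = (J/d) xi_d(J) V^(1/d)` and the perimeter
#' `a = (d/xi_d(J)) V^((d-1)/d)`.
#'
#' @inheritParams xi_factor
#' @param V cell volume(s) (length^d), positive.
#' @return A tibble with columns `V`, `r`, `V_over_aij`, `a`.
#' @examples
#' shape_relations(2, 4, 4)  # square of area 4: inradius 1
#' @export
shape_relations <- function(d, J, V, xi_override = NULL) {
  V <- as.numeric(V)
  if (any(V <= 0)) abort("`V` must be positive.")
  xi <- xi_factor(d, J, xi_override)
  tibble(
    V = V,
    r = xi * V^(1 / d),
    V_over_aij = (1 / d) * (if (is.infinite(J[1])) Inf else J) * xi * V^(1 / d),
    a = (d / xi) * V^((d - 1) / d))
}
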