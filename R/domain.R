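#' Rectangular simulation domain
#'
#' A box in 1, 2 or 3 dimensions.  Tessellation supports d = 1 and 2; the
#' 3D case only enters through the scalar shape relations of
#' [xi_factor()] and [shape_relations()].
#'
#' @param lower,upper numeric vectors of equal length (1--3) with
#'   `lower[k] < upper[k]` on every axis, in length units.
#' @return An object of class `sim_domain` with fields `d`, `lower`,
#'   `upper`.
#' @examples
#' sim_domain(0, 37)           # 1D interval
#' sim_domain(c(0, 0), c(40, 40))  # 2D square
#' @export
sim_domain <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  d <- length(lower)
  if (length(upper) != d) abort("`lower` and `upper` must have equal length.")
  if (!d %in% 1:3) abort("domain dimension must be 1, 2 or 3.")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    abort("domain bounds must be finite.")
  if (any(upper <= lower)) abort("`upper` must exceed `lower` on every axis.")
  structure(list(d = d, lower = lower, upper = upper), class = "sim_domain")
}

#' @export
print.sim_domain <- function(x, ...) {
  cat("<sim_domain> d =", x$d, ": [",
      paste(sprintf("%g, %g", x$lower, x$upper), collapse = "] x ["), "]\n")
  invisible(x)
}

domain_measure <- function(domain) prod(domain$upper - domain$lower)

#' @noRd
check_inside <- function(coords, domain, strict = TRUE) {
  m <- as.matrix(coords)
  for (k in seq_len(domain$d)) {
    bad <- if (strict)
      m[, k] <= domain$lower[k] | m[, k] >= domain$upper[k]
    else
      m[, k] < domain$lower[k] | m[, k] > domain$upper[k]
    if (any(bad))
      abort(paste0("cell centers outside the domain on axis ", k, ": index ",
                   paste(head(which(bad), 5L), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Coerce a data frame of coordinates to a coordinate matrix
#' @noRd
coord_matrix <- function(centers, d = NULL) {
  if (is.matrix(centers)) m <- centers
  else {
    cols <- intersect(c("x", "y", "z"), names(centers))
    if (length(cols) == 0) abort("`centers` needs coordinate columns x[, y[, z]].")
    m <- as.matrix(centers[cols])
  }
  storage.mode(m) <- "double"
  if (!is.null(d) && ncol(m) != d)
    abort(sprintf("expected %d coordinate column(s), found %d.", d, ncol(m)))
  m
}
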