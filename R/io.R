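#' Read and write cell-center and tessellation tables
#'
#' Center sets are plain CSV with header `x[,y]`; tessellation summaries
#' are CSV with columns `cell_id, V, a, n_neighbors, is_boundary`.
#'
#' @param path file path.
#' @param centers data frame with `x[, y]` columns.
#' @param tess a `tessellation`.
#' @return `read_centers_csv()` returns a tibble; the writers return
#'   `path` invisibly.
#' @export
read_centers_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  if (!"x" %in% names(df)) abort("centers file must have an `x` column.")
  df
}

#' @rdname read_centers_csv
#' @export
write_centers_csv <- function(centers, path) {
  cols <- intersect(c("x", "y"), names(centers))
  write.csv(as.data.frame(centers)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_centers_csv
#' @export
write_tessellation_csv <- function(tess, path) {
  df <- data.frame(cell_id = tess$cells$cell, V = tess$cells$V,
                   a = tess$cells$a, n_neighbors = tess$cells$n_neighbors,
                   is_boundary = tess$cells$boundary)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and write simulation configurations
#'
#' Configurations are YAML maps whose sections mirror the package's
#' constructors: `force$cbm_exp` (keys `mu, s, c, r_A, eta`),
#' `force$cbm_poly` (`c_r, c_a, r_R, r_A, n, eta`), `force$wo`
#' (`sigma, kappa, eta`), `force$nh`
#' (`lambda, beta, gamma, V0, a0, eta`), and `pressure`
#' (`kind, d, J, mu`).
#'
#' @param path YAML file path.
#' @param config a named list.
#' @return `read_sim_config()` returns the list; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) yaml::read_yaml(path)

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build force laws and pressure laws from a configuration list
#'
#' @param config a configuration list (see [read_sim_config()]).
#' @return a named list of constructed objects (one per present
#'   section), e.g. `$cbm_exp` (`force_law`), `$wo` (`wo_params`),
#'   `$pressure` (`pressure_law`).
#' @export
laws_from_config <- function(config) {
  out <- list()
  f <- config$force
  if (!is.null(f$cbm_exp))
    out$cbm_exp <- do.call(exp_force, f$cbm_exp)
  if (!is.null(f$cbm_poly))
    out$cbm_poly <- do.call(poly_force, f$cbm_poly)
  if (!is.null(f$wo))
    out$wo <- do.call(wo_params, f$wo)
  if (!is.null(f$nh))
    out$nh <- do.call(nh_params, f$nh)
  pr <- config$pressure
  if (!is.null(pr)) {
    out$pressure <- switch(pr$kind,
      cbm = pressure_law_cbm(out$cbm_exp %||% out$cbm_poly,
                             d = pr$d, J = pr$J %||% default_J(pr$d),
                             mu = pr$mu %||% (out$cbm_exp %||% out$cbm_poly)$mu),
      weliky_oster = pressure_law_wo(out$wo, J = pr$J %||% 6,
                                     mu = pr$mu %||% 1),
      power_law = pressure_law_power(pr$K, pr$gamma),
      abort("unknown pressure kind in config."))
  }
  out
}
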