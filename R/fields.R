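#' Monthly climate field
#'
#' A single variable's 12 monthly long-term-mean grids on a regular
#' lon/lat grid, the basic currency passed between the ingest,
#' downscaling and bioclim stages. Values are stored as an
#' `n_cells x 12` matrix in canonical cell order (see [grid_centers()]);
#' masked cells are `NA`.
#'
#' @param values numeric `n_cells x 12` matrix (or a length-12 vector for
#'   a one-cell grid); column m is calendar month m.
#' @param grid a [grid_spec()].
#' @param variable one of `"pr"`, `"tas"`, `"tasmax"`, `"tasmin"` (or a
#'   derived name).
#' @param units unit tag, e.g. `"K"`, `"degC"`, `"kg m-2 s-1"`,
#'   `"mm/month"`.
#' @param scenario scenario tag, e.g. `"modern"` or `"lgm"`.
#' @param model_id identifier of the source model.
#' @return an object of class `monthly_climate_field` (a list with the
#'   above components).
#' @export
monthly_field <- function(values, grid, variable, units,
                          scenario = "modern", model_id = "unknown") {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  if (ncol(values) != 12) stop("a monthly field needs exactly 12 months")
  if (nrow(values) != grid$n_cells) {
    stop("values has ", nrow(values), " rows but the grid has ",
         grid$n_cells, " cells")
  }
  # flux fields may still carry corrupt negatives; convert_units flags them
  if (units == "mm/month" && any(values < 0, na.rm = TRUE)) {
    stop("negative precipitation values are not allowed")
  }
  structure(
    list(values = values, grid = grid, variable = variable, units = units,
         scenario = scenario, model_id = model_id),
    class = "monthly_climate_field")
}

#' @export
print.monthly_climate_field <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "monthly_climate_field: %s [%s] %s/%s, %d cells x 12 months, range [%.3g, %.3g]\n",
    x$variable, x$units, x$model_id, x$scenario, nrow(x$values),
    rng[1], rng[2]))
  print(x$grid)
  invisible(x)
}

# Per-month climate-change trend between two scenarios on the native grid.
new_anomaly_field <- function(values, grid, kind, variable,
                              model_id = "unknown", flagged = integer(0)) {
  structure(
    list(values = values, grid = grid, kind = kind, variable = variable,
         model_id = model_id, flagged = flagged),
    class = "anomaly_field")
}

#' @export
print.anomaly_field <- function(x, ...) {
  cat(sprintf(
    "anomaly_field (%s trend): %s, %d cells x 12 months, %d flagged cells\n",
    x$kind, x$variable, nrow(x$values), length(x$flagged)))
  invisible(x)
}
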