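# Ingest of raw monthly GCM series: long-term monthly means and the
# unit conversions (Kelvin -> degrees Celsius; precipitation flux ->
# total monthly precipitation under the 30-day-month convention of the
# 360-day model calendar).

SECONDS_PER_30DAY_MONTH <- 60 * 60 * 24 * 30  # 2,592,000

temp_unit_tags <- c("K", "Kelvin")
flux_unit_tags <- c("kg m-2 s-1", "mm s-1", "mm m-2 s-1")

#' Raw monthly time series of one GCM variable
#'
#' Time-ordered monthly grids straight from a model archive, before
#' averaging: `12 * n_years` columns, January of year 1 first.
#'
#' @param values numeric `n_cells x (12 * n_years)` matrix in canonical
#'   cell order; missing data as `NA`.
#' @param grid a [grid_spec()].
#' @param variable one of `"pr"`, `"tas"`, `"tasmax"`, `"tasmin"`.
#' @param units unit tag; must match the variable family (`"K"` for
#'   temperature, `"kg m-2 s-1"` / `"mm s-1"` for precipitation flux).
#' @param calendar source calendar attribute (e.g. `"360_day"`,
#'   `"standard"`); recorded for provenance.
#' @param model_id,scenario,ensemble_member provenance metadata
#'   (ensemble member e.g. `"r1i1p1"`).
#' @return an object of class `raw_monthly_series`.
#' @export
raw_monthly_series <- function(values, grid, variable, units,
                               calendar = "360_day", model_id = "unknown",
                               scenario = "modern",
                               ensemble_member = "r1i1p1") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (ncol(values) %% 12 != 0) {
    stop("series length (", ncol(values), ") is not divisible by 12")
  }
  if (nrow(values) != grid$n_cells) {
    stop("values has ", nrow(values), " rows but the grid has ",
         grid$n_cells, " cells")
  }
  fam_ok <- if (variable %in% c("tas", "tasmax", "tasmin")) {
    units %in% temp_unit_tags
  } else if (variable == "pr") {
    units %in% flux_unit_tags
  } else {
    TRUE
  }
  if (!fam_ok) {
    stop("units tag '", units, "' does not match variable '", variable, "'")
  }
  structure(list(values = values, grid = grid, variable = variable,
                 units = units, calendar = calendar, model_id = model_id,
                 scenario = scenario, ensemble_member = ensemble_member,
                 n_years = ncol(values) %/% 12),
            class = "raw_monthly_series")
}

#' Long-term monthly mean of a raw series
#'
#' Averages each calendar month over all available years, the first step
#' in preparing GCM layers for comparison. Missing values within a
#' cell-month are skipped; the cell-month is masked (`NA`) only when no
#' year contributes data.
#'
#' @param series a [raw_monthly_series()] spanning at least one year.
#' @return a [monthly_field()] with the same grid and units.
#' @export
long_term_monthly_mean <- function(series) {
  stopifnot(inherits(series, "raw_monthly_series"))
  nm <- ncol(series$values)
  if (nm < 12) stop("series must span at least one full year")
  out <- vapply(1:12, function(m) {
    cols <- seq(m, nm, by = 12)
    rowMeans(series$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(series$values)))
  out[is.nan(out)] <- NA_real_  # all contributing years missing
  monthly_field(out, series$grid, series$variable, series$units,
                series$scenario, series$model_id)
}

#' Convert a field to degrees Celsius / mm per month
#'
#' Temperature fields tagged Kelvin are shifted by -273.15 to degrees
#' Celsius. Precipitation flux (per-second units) is converted to total
#' monthly precipitation, by default assuming a 30-day month as in the
#' 360-day model calendar (factor 2,592,000 s). Already-converted fields
#' (tags `"degC"` / `"mm/month"`) are returned unchanged.
#'
#' @param field a [monthly_field()].
#' @param month_days days per month used for the flux conversion
#'   (default 30); set to physical month lengths to override the
#'   360-day-calendar convention.
#' @return a [monthly_field()] in `"degC"` or `"mm/month"`.
#' @export
convert_units <- function(field, month_days = 30) {
  stopifnot(inherits(field, "monthly_climate_field"))
  if (field$units %in% c("degC", "mm/month")) return(field)
  if (field$units %in% temp_unit_tags) {
    return(monthly_field(field$values - 273.15, field$grid, field$variable,
                         "degC", field$scenario, field$model_id))
  }
  if (field$units %in% flux_unit_tags) {
    if (any(field$values < 0, na.rm = TRUE)) {
      stop("negative precipitation flux: corrupt input")
    }
    month_days <- rep_len(month_days, 12)
    fac <- matrix(60 * 60 * 24 * month_days, nrow(field$values), 12,
                  byrow = TRUE)
    return(monthly_field(field$values * fac, field$grid, field$variable,
                         "mm/month", field$scenario, field$model_id))
  }
  stop("unknown units tag: '", field$units, "'")
}

#' Normalize grid orientation
#'
#' Reorders a set of gridded values read from an arbitrary source
#' orientation (e.g. 0-360 longitudes, descending latitudes) to the
#' package's canonical orientation: longitudes in \[-180, 180) ascending
#' and latitudes ascending, longitude varying fastest.
#'
#' @param lon,lat coordinate vectors of the source grid (lengths `nlon`,
#'   `nlat`).
#' @param values matrix with `nlon * nlat` rows (source order: longitude
#'   fastest within each source latitude) and any number of columns.
#' @return list with the reordered `values`, ascending `lon` (wrapped to
#'   \[-180, 180)) and ascending `lat`.
#' @export
normalize_grid_orientation <- function(lon, lat, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lon) * length(lat))
  lon <- ((lon + 180) %% 360) - 180
  olon <- order(lon)
  olat <- order(lat)
  idx <- as.vector(outer(olon, (olat - 1) * length(lon), "+"))
  list(values = values[idx, , drop = FALSE], lon = lon[olon],
       lat = sort(lat))
}
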