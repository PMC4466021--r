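#' Regular longitude/latitude grid specification
#'
#' Defines a regular cell-centre-registered lon/lat grid, e.g. the native
#' 1-4 degree grids of general circulation models or the 0.5 degree
#' target grid of the downscaled layers. Cell centres are placed half a
#' resolution step inside the bounds, so a global 0.5 degree grid has
#' centres at -179.75...179.75 and -89.75...89.75.
#'
#' @param resolution cell size in decimal degrees (> 0).
#' @param lon_range,lat_range numeric length-2 bounds in degrees;
#'   longitudes in \[-180, 180\], latitudes in \[-90, 90\]. The extent must
#'   be an integer multiple of `resolution`.
#' @return an object of class `grid_spec` with components `resolution`,
#'   `lon_range`, `lat_range`, the centre vectors `lon` (ascending) and
#'   `lat` (ascending), `nlon`, `nlat` and `n_cells`.
#' @examples
#' g <- grid_spec(2)          # global 2 degree grid, 90 x 180 cells
#' g$n_cells
#' @export
grid_spec <- function(resolution, lon_range = c(-180, 180),
                      lat_range = c(-90, 90)) {
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution > 0,
            length(lon_range) == 2, length(lat_range) == 2)
  lon_range <- sort(as.numeric(lon_range))
  lat_range <- sort(as.numeric(lat_range))
  if (lon_range[1] < -180 || lon_range[2] > 180) {
    stop("lon_range must lie within [-180, 180]")
  }
  if (lat_range[1] < -90 || lat_range[2] > 90) {
    stop("lat_range must lie within [-90, 90]")
  }
  nlon <- diff(lon_range) / resolution
  nlat <- diff(lat_range) / resolution
  if (abs(nlon - round(nlon)) > 1e-8 || abs(nlat - round(nlat)) > 1e-8) {
    stop("grid extent must be an integer multiple of the resolution")
  }
  nlon <- as.integer(round(nlon))
  nlat <- as.integer(round(nlat))
  if (nlon < 1 || nlat < 1) stop("grid must contain at least one cell")
  g <- list(
    resolution = resolution,
    lon_range = lon_range,
    lat_range = lat_range,
    lon = lon_range[1] + resolution * (seq_len(nlon) - 0.5),
    lat = lat_range[1] + resolution * (seq_len(nlat) - 0.5),
    nlon = nlon,
    nlat = nlat,
    n_cells = nlon * nlat
  )
  class(g) <- "grid_spec"
  g
}

#' Cell-centre coordinates of a grid
#'
#' Returns one row per cell in canonical cell order: longitude varies
#' fastest, latitude ascends (south to north). All gridded values in the
#' package (columns of a [monthly_field()], maps, masks) follow this
#' order.
#'
#' @param grid a [grid_spec()].
#' @return data.frame with columns `lon`, `lat` and `n_cells` rows.
#' @export
grid_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  data.frame(
    lon = rep(grid$lon, times = grid$nlat),
    lat = rep(grid$lat, each = grid$nlon)
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %.4g deg, lon [%g, %g], lat [%g, %g], %d x %d = %d cells\n",
    x$resolution, x$lon_range[1], x$lon_range[2],
    x$lat_range[1], x$lat_range[2], x$nlat, x$nlon, x$n_cells))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-8) {
  inherits(a, "grid_spec") && inherits(b, "grid_spec") &&
    abs(a$resolution - b$resolution) < tol &&
    all(abs(a$lon_range - b$lon_range) < tol) &&
    all(abs(a$lat_range - b$lat_range) < tol)
}
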