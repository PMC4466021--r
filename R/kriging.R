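# Ordinary kriging from the k nearest observations, the workhorse of the
# change-factor downscaling.

target_coords <- function(target) {
  if (inherits(target, "grid_spec")) return(grid_centers(target))
  target <- as.data.frame(target)
  stopifnot(all(c("lon", "lat") %in% names(target)))
  target[, c("lon", "lat")]
}

# Drop missing observations, average duplicate locations, and order by
# (lat, lon) so nearest-neighbour ties resolve deterministically.
prepare_obs <- function(lon, lat, z) {
  keep <- is.finite(z)
  lon <- lon[keep]; lat <- lat[keep]; z <- z[keep]
  key <- paste(signif(lon, 12), signif(lat, 12))
  if (anyDuplicated(key)) {
    z <- as.vector(tapply(z, key, mean))
    lon <- as.vector(tapply(lon, key, function(v) v[1]))
    lat <- as.vector(tapply(lat, key, function(v) v[1]))
  }
  o <- order(lat, lon)
  list(lon = lon[o], lat = lat[o], z = z[o])
}

#' Ordinary kriging to a target grid
#'
#' Predicts each target location from its `n_neighbors` nearest
#' observations by ordinary kriging under a spherical variogram: the
#' (k+1)-dimensional linear system with a Lagrange multiplier enforcing
#' that the weights sum to one is solved per target cell. Duplicate
#' observation locations are averaged before solving; targets whose
#' kriging system remains singular are masked (`NA`) and counted.
#'
#' @param lon,lat,z observation coordinates (degrees) and values;
#'   typically the native-grid cell centres of a GCM.
#' @param model a fitted [variogram_model()].
#' @param target a [grid_spec()] or a data.frame with `lon`, `lat`.
#' @param n_neighbors size of the kriging neighbourhood (default 12).
#' @param metric `"euclidean"` (degrees; default, matching the
#'   unprojected-coordinate convention) or `"haversine"`.
#' @return numeric vector of predictions in target order, with
#'   attributes `weight_sums` (sum of kriging weights per target, 1 up
#'   to solver tolerance) and `n_singular`.
#' @export
krige_to_grid <- function(lon, lat, z, model, target, n_neighbors = 12,
                          metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "variogram_model"))
  obs <- prepare_obs(lon, lat, z)
  if (length(obs$z) < n_neighbors) {
    stop("need at least n_neighbors = ", n_neighbors, " observations, got ",
         length(obs$z))
  }
  tc <- target_coords(target)
  res <- cpp_knn_interp(obs$lon, obs$lat, obs$z, tc$lon, tc$lat,
                        as.integer(n_neighbors), 0L,
                        model$nugget, model$partial_sill, model$range,
                        2, metric == "haversine")
  structure(res$pred, weight_sums = res$wsum, n_singular = res$n_singular)
}

#' Fit a variogram and krige a set of scattered values
#'
#' Convenience wrapper: builds the omnidirectional sample variogram of
#' the observations, fits a spherical model and kriges to the target.
#'
#' @inheritParams krige_to_grid
#' @param ... passed to [empirical_variogram()].
#' @return list with `pred` (as from [krige_to_grid()]) and the fitted
#'   `model`.
#' @export
krige_auto <- function(lon, lat, z, target, n_neighbors = 12, ...) {
  sv <- empirical_variogram(lon, lat, z, ...)
  model <- suppressWarnings(fit_spherical_variogram(sv))
  list(pred = krige_to_grid(lon, lat, z, model, target, n_neighbors),
       model = model)
}
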