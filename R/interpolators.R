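# Alternative interpolation methods used in the accuracy benchmark:
# inverse distance weighting, thin-plate splines and a 12th-degree
# trend surface. Natural-neighbour interpolation is feature-flagged and
# not provided by this build; the benchmark runs with whichever methods
# are available.

#' Inverse distance weighting from the k nearest observations
#'
#' Weights proportional to `1 / distance^power` over the `n_neighbors`
#' nearest observations (the same neighbourhood size as the kriging it
#' is benchmarked against). A target coinciding with an observation
#' returns the observed value (distance-zero dominance).
#'
#' @inheritParams krige_to_grid
#' @param power IDW power (default 2).
#' @return numeric vector of predictions in target order.
#' @export
interpolate_idw <- function(lon, lat, z, target, n_neighbors = 12,
                            power = 2,
                            metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  obs <- prepare_obs(lon, lat, z)
  tc <- target_coords(target)
  res <- cpp_knn_interp(obs$lon, obs$lat, obs$z, tc$lon, tc$lat,
                        as.integer(min(n_neighbors, length(obs$z))), 1L,
                        0, 1, 1, power, metric == "haversine")
  res$pred
}

tps_basis <- function(d) {
  # r^2 log r radial basis, 0 at r = 0
  out <- d * d * log(d)
  out[d == 0] <- 0
  out
}

# Exact classical TPS: solve the augmented [K P; P' 0] system.
tps_solve <- function(lon, lat, z) {
  n <- length(z)
  K <- tps_basis(point_distances(lon, lat, lon, lat))
  P <- cbind(1, lon, lat)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(z, 0, 0, 0))
  list(w = sol[1:n], a = sol[n + 1:3], lon = lon, lat = lat)
}

tps_eval <- function(fit, lon, lat) {
  B <- tps_basis(point_distances(lon, lat, fit$lon, fit$lat))
  drop(B %*% fit$w) + fit$a[1] + fit$a[2] * lon + fit$a[3] * lat
}

# Smooth 0->1 ramp over one overlap width; tiles blend with
# cosine-squared partition-of-unity weights.
pou_ramp <- function(u) {
  v <- pmin(pmax(u, 0), 1)
  sin(v * pi / 2)^2
}

#' Thin-plate spline interpolation
#'
#' Classical thin-plate spline (radial basis r^2 log r with an affine
#' part) interpolating the observations exactly. Point sets small
#' enough for one dense solve (`<= max_dense`) use the full augmented
#' system; larger sets are solved by a partition of unity: exact local
#' thin-plate splines on overlapping rectangular tiles, blended with
#' smooth cosine-squared weights. Both paths are deterministic and
#' reproduce the observed values at observation locations.
#'
#' @inheritParams krige_to_grid
#' @param max_dense largest point count solved as a single dense system
#'   (default 1500).
#' @param tile_deg core tile width in degrees for the partition-of-unity
#'   path (default 36).
#' @param overlap_deg tile overlap (and blending ramp width) in degrees
#'   (default 12).
#' @return numeric vector of predictions in target order.
#' @export
interpolate_tps <- function(lon, lat, z, target, max_dense = 1500,
                            tile_deg = 36, overlap_deg = 12) {
  obs <- prepare_obs(lon, lat, z)
  n <- length(obs$z)
  if (n < 3) stop("thin-plate spline needs at least 3 points")
  tc <- target_coords(target)
  if (n <= max_dense) {
    return(tps_eval(tps_solve(obs$lon, obs$lat, obs$z), tc$lon, tc$lat))
  }
  lo <- range(obs$lon)
  la <- range(obs$lat)
  nx <- max(1, ceiling(diff(lo) / tile_deg))
  ny <- max(1, ceiling(diff(la) / tile_deg))
  xs <- seq(lo[1], lo[2], length.out = nx + 1)
  ys <- seq(la[1], la[2], length.out = ny + 1)
  num <- numeric(nrow(tc))
  den <- numeric(nrow(tc))
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      x0 <- xs[i] - overlap_deg; x1 <- xs[i + 1] + overlap_deg
      y0 <- ys[j] - overlap_deg; y1 <- ys[j + 1] + overlap_deg
      oi <- obs$lon >= x0 & obs$lon <= x1 & obs$lat >= y0 & obs$lat <= y1
      ti <- tc$lon >= x0 & tc$lon <= x1 & tc$lat >= y0 & tc$lat <= y1
      if (!any(ti) || sum(oi) < 4) next
      fit <- tps_solve(obs$lon[oi], obs$lat[oi], obs$z[oi])
      p <- tps_eval(fit, tc$lon[ti], tc$lat[ti])
      w <- pou_ramp((tc$lon[ti] - x0) / overlap_deg) *
        pou_ramp((x1 - tc$lon[ti]) / overlap_deg) *
        pou_ramp((tc$lat[ti] - y0) / overlap_deg) *
        pou_ramp((y1 - tc$lat[ti]) / overlap_deg)
      num[ti] <- num[ti] + w * p
      den[ti] <- den[ti] + w
    }
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Polynomial trend-surface interpolation
#'
#' Least-squares fit of a bivariate polynomial in (lon, lat) of the
#' given degree, using orthogonalized polynomial terms (raw high-degree
#' monomials in degrees are numerically unusable). Degree 12 is the
#' benchmark's configuration.
#'
#' @inheritParams krige_to_grid
#' @param degree polynomial degree (default 12).
#' @return numeric vector of predictions in target order.
#' @export
interpolate_trend_surface <- function(lon, lat, z, target, degree = 12) {
  obs <- prepare_obs(lon, lat, z)
  n_coef <- choose(degree + 2, 2)
  if (length(obs$z) < n_coef) {
    stop("trend surface of degree ", degree, " needs at least ", n_coef,
         " points, got ", length(obs$z))
  }
  tc <- target_coords(target)
  df <- data.frame(lon = obs$lon, lat = obs$lat, z = obs$z)
  if (stats::var(obs$z) == 0) return(rep(obs$z[1], nrow(tc)))
  fit <- lm(z ~ poly(lon, lat, degree = degree), data = df)
  unname(predict(fit, newdata = tc))
}

#' Dispatch an alternative interpolation method by name
#'
#' @inheritParams krige_to_grid
#' @param method one of `"idw"`, `"thin_plate_spline"`,
#'   `"trend_surface_deg12"`, `"natural_neighbor"`.
#' @param ... passed to the method.
#' @return numeric vector of predictions in target order.
#' @export
interpolate_alternative <- function(lon, lat, z, target,
                                    method = c("idw", "thin_plate_spline",
                                               "trend_surface_deg12",
                                               "natural_neighbor"),
                                    ...) {
  method <- match.arg(method)
  switch(method,
    idw = interpolate_idw(lon, lat, z, target, ...),
    thin_plate_spline = interpolate_tps(lon, lat, z, target, ...),
    trend_surface_deg12 = interpolate_trend_surface(lon, lat, z, target,
                                                    degree = 12, ...),
    natural_neighbor = stop(
      "natural-neighbour interpolation is not available in this build; ",
      "run the benchmark with the other methods"))
}
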