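# Change-factor (delta) downscaling: climate-change trends at native
# resolution, kriging of trends and modern climate to the target grid,
# and re-application of the trends; plus the interpolation-accuracy
# (MSE resampling) benchmark.

#' Climate-change trend between LGM and modern conditions
#'
#' Temperature trends are simple differences (LGM - modern) per month
#' and cell; precipitation trends are ratios (LGM - modern) / modern.
#' Where modern precipitation is zero the ratio is 0 if LGM is also
#' zero; otherwise the ratio is computed against a floor of
#' `eps` mm/month and the cell is flagged (the printed ratio formula is
#' undefined at zero modern precipitation).
#'
#' @param lgm,modern [monthly_field()]s of the same variable, model and
#'   grid.
#' @param kind `"difference"` (temperature) or `"ratio"`
#'   (precipitation); defaults from the variable family.
#' @param eps modern-precipitation floor for the ratio at zero-rain
#'   cells (mm/month).
#' @return an `anomaly_field` on the native grid; `$flagged` holds the
#'   indices of floored cells.
#' @export
compute_climate_change_trend <- function(lgm, modern, kind = NULL,
                                         eps = 0.1) {
  stopifnot(inherits(lgm, "monthly_climate_field"),
            inherits(modern, "monthly_climate_field"))
  if (!same_grid(lgm$grid, modern$grid)) {
    stop("LGM and modern fields are on different grids")
  }
  if (lgm$variable != modern$variable) {
    stop("LGM and modern fields are different variables")
  }
  if (is.null(kind)) {
    kind <- if (lgm$variable == "pr") "ratio" else "difference"
  }
  kind <- match.arg(kind, c("difference", "ratio"))
  flagged <- integer(0)
  if (kind == "difference") {
    vals <- lgm$values - modern$values
  } else {
    m <- modern$values
    zero <- which(m == 0)
    both_zero <- zero[lgm$values[zero] == 0]
    floored <- setdiff(zero, both_zero)
    m[floored] <- eps
    vals <- (lgm$values - m) / m
    vals[both_zero] <- 0
    flagged <- floored
  }
  new_anomaly_field(vals, lgm$grid, kind, lgm$variable, lgm$model_id,
                    flagged = flagged)
}

#' Apply an interpolated trend to an interpolated modern climate
#'
#' The final change-factor step: `LGM = modern + trend` for difference
#' trends, `LGM = modern * (1 + trend)` for ratio trends.
#' Reconstructed precipitation below zero (possible after interpolation
#' overshoot) is clipped to 0; the clip count is recorded in the
#' result's `n_clipped` attribute.
#'
#' @param modern_interp a [monthly_field()] on the target grid.
#' @param trend_interp an `anomaly_field` on the same grid (e.g. kriged
#'   trends repacked via [compute_climate_change_trend()] outputs).
#' @return a [monthly_field()] of the reconstructed LGM climate.
#' @export
apply_trend <- function(modern_interp, trend_interp) {
  stopifnot(inherits(modern_interp, "monthly_climate_field"),
            inherits(trend_interp, "anomaly_field"))
  if (!same_grid(modern_interp$grid, trend_interp$grid)) {
    stop("modern and trend fields are on different grids")
  }
  if (trend_interp$kind == "difference") {
    vals <- modern_interp$values + trend_interp$values
    n_clipped <- 0L
  } else {
    vals <- modern_interp$values * (1 + trend_interp$values)
    neg <- which(vals < 0)
    vals[neg] <- 0
    n_clipped <- length(neg)
  }
  out <- monthly_field(vals, modern_interp$grid, modern_interp$variable,
                       modern_interp$units, "lgm", modern_interp$model_id)
  attr(out, "n_clipped") <- n_clipped
  out
}

# Krige one set of monthly surfaces (a field or anomaly) from its native
# grid to the target grid, fitting a spherical variogram per month.
krige_monthly <- function(values, native_grid, target_grid,
                          n_neighbors = 12, ...) {
  centers <- grid_centers(native_grid)
  out <- matrix(NA_real_, target_grid$n_cells, 12)
  models <- vector("list", 12)
  for (m in 1:12) {
    z <- values[, m]
    sv <- empirical_variogram(centers$lon, centers$lat, z, ...)
    model <- suppressWarnings(fit_spherical_variogram(sv))
    out[, m] <- krige_to_grid(centers$lon, centers$lat, z, model,
                              target_grid, n_neighbors)
    models[[m]] <- model
  }
  list(values = out, models = models)
}

#' Change-factor downscaling of one GCM variable
#'
#' The full three-step procedure for one raw variable of one GCM:
#' (i) compute the monthly climate-change trend (difference or ratio)
#' at the model's native resolution, (ii) krige the trend and the modern
#' climate independently per month to the target grid (spherical
#' variogram fitted per surface, 12 nearest observations), and
#' (iii) apply the interpolated trend to the interpolated modern climate
#' to obtain the downscaled LGM layer.
#'
#' @param modern,lgm [monthly_field()]s on the native grid, in degC or
#'   mm/month.
#' @param target_grid the output [grid_spec()] (typically 0.5 degrees).
#' @param n_neighbors kriging neighbourhood size (default 12).
#' @param eps zero-precipitation floor for ratio trends, see
#'   [compute_climate_change_trend()].
#' @param ... passed to [empirical_variogram()].
#' @return list with [monthly_field()]s `modern` and `lgm` on the target
#'   grid, the native-resolution `trend`, its interpolated counterpart
#'   `trend_interp`, and the per-month fitted `variograms` (`modern` and
#'   `trend` lists).
#' @export
downscale_field <- function(modern, lgm, target_grid, n_neighbors = 12,
                            eps = 0.1, ...) {
  stopifnot(inherits(target_grid, "grid_spec"))
  trend <- compute_climate_change_trend(lgm, modern, eps = eps)
  km <- krige_monthly(modern$values, modern$grid, target_grid,
                      n_neighbors, ...)
  kt <- krige_monthly(trend$values, modern$grid, target_grid,
                      n_neighbors, ...)
  modern_i <- monthly_field(km$values, target_grid, modern$variable,
                            modern$units, "modern", modern$model_id)
  trend_i <- new_anomaly_field(kt$values, target_grid, trend$kind,
                               trend$variable, trend$model_id,
                               flagged = trend$flagged)
  lgm_i <- apply_trend(modern_i, trend_i)
  list(modern = modern_i, lgm = lgm_i, trend = trend, trend_interp = trend_i,
       variograms = list(modern = km$models, trend = kt$models))
}

#' Downscale all four raw variables of one pseudo-GCM
#'
#' Runs [downscale_field()] for `tas`, `tasmax`, `tasmin` and `pr` of
#' one model of a [generate_pseudo_gcm_ensemble()] result (or any list
#' with `modern` / `lgm` entries holding the four fields).
#'
#' @param model_fields one element of `ensemble$models`.
#' @param target_grid the output [grid_spec()].
#' @param ... passed to [downscale_field()].
#' @return named list (per variable) of [downscale_field()] results.
#' @export
downscale_gcm <- function(model_fields, target_grid, ...) {
  vars <- c("tas", "tasmax", "tasmin", "pr")
  setNames(lapply(vars, function(v) {
    downscale_field(model_fields$modern[[v]], model_fields$lgm[[v]],
                    target_grid, ...)
  }), vars)
}

#' Interpolation-accuracy benchmark by repeated random sampling
#'
#' Compares interpolated surfaces against the original layer by the mean
#' square error MSE = (1/n) * sum((X_i - Z_i)^2) over `n_points` cells
#' drawn uniformly without replacement, repeated `n_reps` times — the
#' resampling design used to rank interpolation methods (5000 points,
#' 1000 replicates at full scale).
#'
#' @param original numeric vector of the reference layer Z at the
#'   comparison locations.
#' @param interpolated named list of numeric vectors X (one per method),
#'   each aligned with `original`.
#' @param n_points points per replicate (default 5000); if more than the
#'   available cells, all cells are used with a warning.
#' @param n_reps number of replicates (default 1000).
#' @param seed integer seed making the draws reproducible.
#' @return an object of class `mse_result`: list with `mse` (an
#'   `n_reps x method` matrix), `n_points`, `n_reps` and `seed`.
#' @export
mse_benchmark <- function(original, interpolated, n_points = 5000,
                          n_reps = 1000, seed = 1) {
  stopifnot(is.list(interpolated), length(interpolated) >= 1,
            !is.null(names(interpolated)))
  ok <- Reduce(`&`, lapply(interpolated, is.finite), is.finite(original))
  idx_pool <- which(ok)
  if (n_points > length(idx_pool)) {
    warning("n_points exceeds available cells; using all ",
            length(idx_pool), " cells")
    n_points <- length(idx_pool)
  }
  mse <- with_preserved_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      s <- idx_pool[sample.int(length(idx_pool), n_points)]
      vapply(interpolated,
             function(x) mean((x[s] - original[s])^2), numeric(1))
    }, numeric(length(interpolated)))
  })
  mse <- matrix(mse, nrow = n_reps, ncol = length(interpolated),
                byrow = TRUE, dimnames = list(NULL, names(interpolated)))
  structure(list(mse = mse, n_points = n_points, n_reps = n_reps,
                 seed = seed),
            class = "mse_result")
}

#' @export
print.mse_result <- function(x, ...) {
  cat(sprintf("mse_result: %d replicates of %d points\n",
              x$n_reps, x$n_points))
  print(apply(x$mse, 2, stats::median))
  invisible(x)
}
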