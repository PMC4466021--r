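# Sample variograms and spherical variogram fitting. The sample
# variogram is omnidirectional; the spherical model is fitted by
# weighted least squares with weights N_h / h^2.

#' Spherical variogram model
#'
#' gamma(h) = nugget + partial_sill * (1.5 h/r - 0.5 (h/r)^3) for
#' 0 < h < r, and nugget + partial_sill for h >= r; gamma(0) = 0. The
#' spherical model reaches its sill exactly at the range, mirroring the
#' finite-distance decay of spatial autocorrelation in climate fields.
#'
#' @param nugget nugget semivariance (>= 0).
#' @param partial_sill partial sill (>= 0).
#' @param range range in degrees (> 0).
#' @param converged logical fit-convergence flag.
#' @param residual_norm weighted residual norm of the fit, if fitted.
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(nugget, partial_sill, range, converged = TRUE,
                            residual_norm = NA_real_) {
  if (nugget < 0) stop("nugget must be >= 0")
  if (partial_sill < 0) stop("partial_sill must be >= 0")
  if (range <= 0) stop("range must be > 0")
  structure(list(nugget = nugget, partial_sill = partial_sill,
                 range = range, model = "spherical", converged = converged,
                 residual_norm = residual_norm),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "spherical variogram: nugget %.4g, partial sill %.4g, range %.4g%s\n",
    x$nugget, x$partial_sill, x$range,
    if (isTRUE(x$converged)) "" else " [fit did not converge]"))
  invisible(x)
}

#' Evaluate a spherical variogram
#'
#' @param model a [variogram_model()].
#' @param h lag distances (same units as the range).
#' @return semivariances gamma(h).
#' @export
vgm_gamma <- function(model, h) {
  u <- pmin(h / model$range, 1)
  ifelse(h <= 0, 0, model$nugget + model$partial_sill * (1.5 * u - 0.5 * u^3))
}

#' Omnidirectional sample variogram of scattered observations
#'
#' Bins all point pairs by separation distance and returns the mean
#' semivariance 0.5 * mean((z_i - z_j)^2) per lag bin, by exhaustive
#' pair scan. With `n_max` set (default 3000), larger point sets are
#' subsampled once, reproducibly, before the scan — the standard
#' practical shortcut for variogram estimation on dense grids.
#'
#' @param lon,lat,z observation coordinates (degrees) and values; at
#'   least 2 points (>= 30 are required for a trustworthy downstream
#'   fit).
#' @param n_bins number of equal-width lag bins (default 15).
#' @param cutoff maximum lag; default one third of the bounding-box
#'   diagonal.
#' @param metric `"euclidean"` (degrees; default) or `"haversine"` (km).
#' @param n_max subsample size for large point sets; `Inf` disables.
#' @param subsample_seed seed for the subsample draw.
#' @return an object of class `sample_variogram`: a data.frame with
#'   columns `dist` (mean pair distance per bin), `gamma` and `np`
#'   (pair count), empty bins dropped.
#' @export
empirical_variogram <- function(lon, lat, z, n_bins = 15, cutoff = NULL,
                                metric = c("euclidean", "haversine"),
                                n_max = 3000, subsample_seed = 1) {
  metric <- match.arg(metric)
  keep <- is.finite(z)
  lon <- lon[keep]; lat <- lat[keep]; z <- z[keep]
  n <- length(z)
  if (n < 2) stop("at least 2 points are required")
  if (n > n_max) {
    idx <- with_preserved_seed(subsample_seed, sample.int(n, n_max))
    lon <- lon[idx]; lat <- lat[idx]; z <- z[idx]
  }
  if (is.null(cutoff)) {
    diag_len <- if (metric == "euclidean") {
      sqrt(diff(range(lon))^2 + diff(range(lat))^2)
    } else {
      max(point_distances(lon, lat, lon, lat, metric = "haversine"))
    }
    cutoff <- diag_len / 3
  }
  breaks <- seq(0, cutoff, length.out = n_bins + 1)
  res <- cpp_semivariance_bins(lon, lat, z, breaks,
                               metric == "haversine")
  out <- data.frame(dist = res$dist, gamma = res$gamma, np = res$np)
  out <- out[out$np > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_variogram", "data.frame")
  out
}

# Method-of-moments starting values: nugget from the first lag, sill
# from the high-lag plateau, range where the sample first reaches 95%
# of the plateau.
vgm_init <- function(sv) {
  sill <- mean(sv$gamma[sv$dist >= stats::median(sv$dist)])
  nugget <- max(0, min(sv$gamma[1], sill))
  psill <- max(sill - nugget, 1e-12)
  at_sill <- sv$dist[sv$gamma >= nugget + 0.95 * psill]
  range <- if (length(at_sill)) at_sill[1] else max(sv$dist)
  c(nugget = nugget, psill = psill, range = max(range, 1e-6))
}

#' Fit a spherical variogram to a sample variogram
#'
#' Weighted least squares with weights `np / dist^2`, so short,
#' well-populated lags dominate the fit. On optimizer failure the
#' method-of-moments starting values are returned with
#' `converged = FALSE` (never silently).
#'
#' @param sv a [sample_variogram][empirical_variogram()] with at least 3
#'   nonempty bins.
#' @return a [variogram_model()] with `converged` and `residual_norm`
#'   filled in.
#' @export
fit_spherical_variogram <- function(sv) {
  stopifnot(inherits(sv, "sample_variogram"))
  sv <- sv[sv$np > 0 & is.finite(sv$gamma), , drop = FALSE]
  if (nrow(sv) < 3) stop("at least 3 nonempty lag bins are required")
  w <- sv$np / sv$dist^2
  init <- vgm_init(sv)

  # pure-nugget / flat structure: nothing to optimize
  if (max(sv$gamma) - min(sv$gamma) < 1e-12 * max(max(sv$gamma), 1)) {
    m <- variogram_model(mean(sv$gamma), 0, min(sv$dist),
                         converged = FALSE, residual_norm = 0)
    warning("flat sample variogram: pure-nugget model returned")
    return(m)
  }

  obj <- function(p) {
    g <- ifelse(sv$dist >= p[3], p[1] + p[2],
                p[1] + p[2] * (1.5 * sv$dist / p[3] -
                                 0.5 * (sv$dist / p[3])^3))
    sum(w * (g - sv$gamma)^2)
  }
  fit <- tryCatch(
    optim(init, obj, method = "L-BFGS-B",
          lower = c(0, 0, 1e-6),
          upper = c(Inf, Inf, 4 * max(sv$dist))),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) {
    warning("variogram fit did not converge; ",
            "method-of-moments estimate returned")
    return(variogram_model(init[1], init[2], init[3], converged = FALSE,
                           residual_norm = sqrt(obj(init))))
  }
  variogram_model(fit$par[1], fit$par[2], fit$par[3], converged = TRUE,
                  residual_norm = sqrt(fit$value))
}
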