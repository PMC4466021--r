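# Synthetic pseudo-GCM ensembles: stationary Gaussian random fields with
# spherical covariance, a shared climate signal plus group- and
# model-specific deviations, and latitude-dependent disagreement between
# models in temperature vs precipitation.

#' Random-field parameters
#'
#' Parameters of a stationary Gaussian random field with a spherical
#' covariance structure, used by [generate_gaussian_field()].
#'
#' @param mean field mean, in field units.
#' @param nugget nugget variance (>= 0); realized as spatially
#'   uncorrelated noise.
#' @param sill total sill (variance at large lags, >= nugget).
#' @param range spherical range in degrees (> 0); covariance is exactly
#'   zero beyond it.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical fields.
#' @return an object of class `field_params`.
#' @export
field_params <- function(mean = 0, nugget = 0, sill = 1, range = 10,
                         seed = NULL) {
  if (!is.numeric(nugget) || nugget < 0) stop("nugget must be >= 0")
  if (!is.numeric(sill) || sill < nugget) stop("sill must be >= nugget")
  if (!is.numeric(range) || range <= 0) stop("range must be > 0")
  structure(list(mean = mean, nugget = nugget, sill = sill, range = range,
                 seed = seed),
            class = "field_params")
}

# Spherical correlation core: 1 - gamma/sill for a zero-nugget spherical
# variogram; compact support at u = h/range >= 1.
sph_corr <- function(u) {
  ifelse(u >= 1, 0, 1 - (1.5 * u - 0.5 * u^3))
}

# Simulate `n` independent realizations of a zero-mean stationary field
# with spherical covariance (partial sill `psill`, range in degrees) on a
# regular grid, by circulant embedding on a doubled torus (exact up to
# clamping of numerically negative spectral mass, which the compact
# support of the spherical model keeps negligible). Returns an
# n_cells x n matrix in canonical cell order.
sim_spherical_grf <- function(grid, psill, range, n = 1) {
  if (psill <= 0) return(matrix(0, grid$n_cells, n))
  h <- grid$resolution
  m_lon <- stats::nextn(2L * grid$nlon, c(2, 3, 5))
  m_lat <- stats::nextn(2L * grid$nlat, c(2, 3, 5))
  # wrap-around lags on the embedding torus
  dlon <- h * pmin(0:(m_lon - 1), m_lon - (0:(m_lon - 1)))
  dlat <- h * pmin(0:(m_lat - 1), m_lat - (0:(m_lat - 1)))
  d <- sqrt(outer(dlon^2, dlat^2, "+"))
  cc <- psill * sph_corr(d / range)
  lambda <- Re(stats::fft(cc))
  neg <- min(lambda)
  if (neg < -1e-6 * max(lambda)) {
    warning("circulant embedding not nonnegative definite; ",
            "clamping negative spectral mass")
  }
  lambda[lambda < 0] <- 0
  scale <- sqrt(lambda / (m_lon * m_lat))
  out <- matrix(0, grid$n_cells, n)
  sel_lon <- seq_len(grid$nlon)
  sel_lat <- seq_len(grid$nlat)
  r <- 1L
  while (r <= n) {
    eps <- matrix(complex(real = rnorm(m_lon * m_lat),
                          imaginary = rnorm(m_lon * m_lat)),
                  m_lon, m_lat)
    zz <- stats::fft(scale * eps)
    out[, r] <- as.vector(Re(zz)[sel_lon, sel_lat])
    if (r + 1L <= n) out[, r + 1L] <- as.vector(Im(zz)[sel_lon, sel_lat])
    r <- r + 2L
  }
  out
}

#' Simulate a monthly field with spherical spatial covariance
#'
#' Generates 12 independent monthly realizations of a stationary
#' Gaussian random field with the requested spherical covariance
#' (nugget + partial sill, compactly supported at the range). Used to
#' emulate the spatial structure of raw GCM variables in tests and
#' benchmarks.
#'
#' @param grid a [grid_spec()] with at least 4 x 4 cells.
#' @param params a [field_params()].
#' @param variable,units,scenario,model_id metadata for the returned
#'   field.
#' @param clip_zero clip negative values to 0 after generation
#'   (precipitation-like fields).
#' @return a [monthly_field()].
#' @examples
#' g <- grid_spec(2, c(-40, 40), c(-30, 30))
#' f <- generate_gaussian_field(g, field_params(sill = 2, range = 10, seed = 1))
#' @export
generate_gaussian_field <- function(grid, params,
                                    variable = "tas", units = "degC",
                                    scenario = "modern",
                                    model_id = "synthetic",
                                    clip_zero = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "field_params"))
  if (grid$nlon < 4 || grid$nlat < 4) stop("grid must have at least 4x4 cells")
  psill <- params$sill - params$nugget
  vals <- with_preserved_seed(params$seed, {
    v <- sim_spherical_grf(grid, psill, params$range, n = 12)
    if (params$nugget > 0) {
      v <- v + matrix(rnorm(length(v), 0, sqrt(params$nugget)), nrow(v))
    }
    v
  })
  vals <- vals + params$mean
  if (clip_zero) vals[vals < 0] <- 0
  monthly_field(vals, grid, variable, units, scenario, model_id)
}

#' Default latitude-dependent disagreement amplitudes
#'
#' Logistic profiles in absolute latitude with midpoint 35 degrees:
#' between-model temperature disagreement grows towards the poles, and
#' precipitation disagreement grows towards the tropics — the
#' latitudinal pattern of between-GCM spread these ensembles emulate.
#'
#' @param lat latitude in degrees.
#' @return amplitude (field units: degC or mm/month) at each latitude.
#' @export
temperature_disagreement <- function(lat) {
  0.8 + 5 * plogis((abs(lat) - 35) / 8)
}

#' @rdname temperature_disagreement
#' @export
precipitation_disagreement <- function(lat) {
  4 + 36 * plogis((35 - abs(lat)) / 8)
}

#' Configuration of a pseudo-GCM ensemble
#'
#' @param n_models number of models (default 9, the size of the LGM
#'   multi-model ensemble the package audits).
#' @param group_labels integer partition of the models into groups of
#'   similar models (default 4 groups over 9 models); models within a
#'   group share a common signal field.
#' @param noise_sd within-group model noise, as a fraction of the group
#'   signal standard deviation (default 0.1).
#' @param disagreement_profile list with functions `tas(lat)` and
#'   `pr(lat)` giving the between-model disagreement amplitude at each
#'   latitude; amplitudes must be >= 0.
#' @param field_range spherical range (degrees) of the signal and noise
#'   fields.
#' @param model_ids optional character ids (default `"GCM01"`...).
#' @param seed integer seed controlling all randomness.
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_models = 9,
                            group_labels = c(1, 2, 2, 3, 3, 3, 4, 4, 4),
                            noise_sd = 0.1,
                            disagreement_profile = list(
                              tas = temperature_disagreement,
                              pr = precipitation_disagreement),
                            field_range = 25,
                            model_ids = NULL,
                            seed = 1) {
  if (n_models < 2) stop("n_models must be >= 2")
  group_labels <- as.integer(group_labels)
  if (length(group_labels) != n_models) {
    stop("group_labels must assign a group to every model")
  }
  if (length(unique(group_labels)) > n_models) {
    stop("more groups than models")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(model_ids)) model_ids <- sprintf("GCM%02d", seq_len(n_models))
  stopifnot(length(model_ids) == n_models)
  structure(list(n_models = n_models, group_labels = group_labels,
                 noise_sd = noise_sd,
                 disagreement_profile = disagreement_profile,
                 field_range = field_range, model_ids = model_ids,
                 seed = seed),
            class = "ensemble_config")
}

# Deterministic background climatologies (degC, mm/month): a latitudinal
# gradient with a hemispherically phased seasonal cycle, cooled/dried
# under the glacial scenario.
clim_tas <- function(lat, month, scenario) {
  base <- 28 - 0.6 * abs(lat)
  if (scenario == "lgm") base <- base - (3 + 0.08 * abs(lat))
  phase <- ifelse(lat >= 0, 1, -1)
  base + 0.35 * abs(lat) * phase * cos(2 * pi * (month - 7) / 12)
}

clim_pr <- function(lat, month, scenario) {
  base <- 25 + 175 * exp(-(lat / 25)^2)
  if (scenario == "lgm") base <- base * 0.75
  peak <- ifelse(lat >= 0, 7, 1)
  base * (1 + 0.3 * cos(2 * pi * (month - peak) / 12))
}

#' Generate a pseudo-GCM ensemble with planted group structure
#'
#' Builds `modern` and `lgm` monthly fields of `tas`, `tasmax`, `tasmin`
#' and `pr` for each model. Every model's field is the shared
#' deterministic climatology plus latitude-modulated deviations
#' `a(lat) * (group signal + noise_sd * model noise)`: an annual-mean
#' component and a (zero-annual-mean) seasonal-amplitude component, so
#' both mean-state and seasonality variables carry the planted group
#' structure. The diurnal half-range separating `tasmax`/`tasmin` from
#' `tas` is likewise group-structured. Group signals are common to all
#' models of a planted group; the amplitude `a(lat)` follows the
#' configured disagreement profile (temperature spread grows poleward,
#' precipitation spread grows towards the tropics). By construction
#' `tasmin <= tas <= tasmax` everywhere and precipitation is clipped at
#' zero.
#'
#' @param config an [ensemble_config()].
#' @param grid a [grid_spec()].
#' @return an object of class `pseudo_gcm_ensemble`: a list with
#'   `models` (per model, per scenario, the four [monthly_field()]s),
#'   `groups` (the planted partition, named by model id), `grid` and
#'   `config`.
#' @export
generate_pseudo_gcm_ensemble <- function(config, grid) {
  stopifnot(inherits(config, "ensemble_config"), inherits(grid, "grid_spec"))
  centers <- grid_centers(grid)
  lat <- centers$lat
  groups <- sort(unique(config$group_labels))
  a_tas <- config$disagreement_profile$tas(lat)
  a_pr <- config$disagreement_profile$pr(lat)
  if (any(a_tas < 0) || any(a_pr < 0)) {
    stop("disagreement amplitudes must be >= 0")
  }

  sims <- with_preserved_seed(config$seed, {
    lapply(c(modern = "modern", lgm = "lgm"), function(scen) {
      grf <- function(n) sim_spherical_grf(grid, 1, config$field_range, n)
      list(g_tas = grf(length(groups)), e_tas = grf(config$n_models),
           g_tas_s = grf(length(groups)), e_tas_s = grf(config$n_models),
           g_pr = grf(length(groups)), e_pr = grf(config$n_models),
           g_pr_s = grf(length(groups)), e_pr_s = grf(config$n_models),
           g_hr = grf(length(groups)), e_hr = grf(config$n_models))
    })
  })

  months <- 1:12
  season <- cos(2 * pi * (months - 7) / 12)  # zero mean over the year
  models <- setNames(vector("list", config$n_models), config$model_ids)
  for (i in seq_len(config$n_models)) {
    gi <- match(config$group_labels[i], groups)
    per_scen <- lapply(c(modern = "modern", lgm = "lgm"), function(scen) {
      s <- sims[[scen]]
      mix <- function(gf, ef) gf[, gi] + config$noise_sd * ef[, i]
      dev_tas <- a_tas * mix(s$g_tas, s$e_tas)
      dev_tas_s <- 0.5 * a_tas * mix(s$g_tas_s, s$e_tas_s)
      dev_pr <- a_pr * mix(s$g_pr, s$e_pr)
      dev_pr_s <- 0.5 * a_pr * mix(s$g_pr_s, s$e_pr_s)
      hr <- 3 + 1.2 * abs(mix(s$g_hr, s$e_hr))
      tas <- vapply(months, function(m) {
        clim_tas(lat, m, scen) + dev_tas + dev_tas_s * season[m]
      }, numeric(grid$n_cells))
      pr <- vapply(months, function(m) {
        pmax(0, clim_pr(lat, m, scen) + dev_pr + dev_pr_s * season[m])
      }, numeric(grid$n_cells))
      list(
        tas = monthly_field(tas, grid, "tas", "degC", scen,
                            config$model_ids[i]),
        tasmax = monthly_field(tas + hr, grid, "tasmax", "degC", scen,
                               config$model_ids[i]),
        tasmin = monthly_field(tas - hr, grid, "tasmin", "degC", scen,
                               config$model_ids[i]),
        pr = monthly_field(pr, grid, "pr", "mm/month", scen,
                           config$model_ids[i])
      )
    })
    models[[i]] <- per_scen
  }
  structure(list(models = models,
                 groups = setNames(config$group_labels, config$model_ids),
                 grid = grid, config = config),
            class = "pseudo_gcm_ensemble")
}

#' @export
print.pseudo_gcm_ensemble <- function(x, ...) {
  cat(sprintf(
    "pseudo_gcm_ensemble: %d models in %d planted groups, %d cells\n",
    length(x$models), length(unique(x$groups)), x$grid$n_cells))
  print(x$grid)
  invisible(x)
}
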