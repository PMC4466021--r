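# Between-GCM agreement statistics on an aligned ensemble of bioclim
# stacks: per-cell standard deviation and quartile coefficient of
# dispersion maps, an all-variable agreement mask, latitudinal profiles
# and region summaries.

#' Aligned multi-model ensemble cube
#'
#' Stacks the bioclim layers of several models into a
#' `cells x models x variables` array on a common grid, the input to all
#' agreement statistics.
#'
#' @param stacks named list of [compute_bioclim()] results (one per
#'   model; >= 2), all on the same grid; plain `n_cells x 19` matrices
#'   with `BIO1`...`BIO19` columns are accepted when `grid` is given.
#' @param grid the common [grid_spec()]; taken from the first stack when
#'   omitted.
#' @return an object of class `ensemble_cube`: a 3-d array with
#'   dimnames `(NULL, model, variable)` and a `grid` attribute.
#' @export
ensemble_cube <- function(stacks, grid = NULL) {
  stopifnot(is.list(stacks), length(stacks) >= 2, !is.null(names(stacks)))
  if (is.null(grid)) grid <- attr(stacks[[1]], "grid")
  stopifnot(inherits(grid, "grid_spec"))
  for (s in stacks) {
    g <- attr(s, "grid")
    if (!is.null(g) && !same_grid(grid, g)) {
      stop("all stacks must share one grid")
    }
    if (nrow(s) != grid$n_cells || ncol(s) != 19) {
      stop("each stack must be n_cells x 19")
    }
  }
  n <- nrow(stacks[[1]])
  cube <- array(NA_real_, c(n, length(stacks), 19),
                dimnames = list(NULL, names(stacks), bio_names()))
  for (i in seq_along(stacks)) {
    s <- as.matrix(unclass(stacks[[i]]))
    if (!is.null(colnames(s))) s <- s[, bio_names(), drop = FALSE]
    cube[, i, ] <- s
  }
  structure(cube, grid = grid, class = c("ensemble_cube", "array"))
}

# cells x models matrix for one variable; robust to one-cell grids
cube_slice <- function(cube, variable) {
  x <- unclass(cube)[, , variable, drop = FALSE]
  matrix(x, dim(cube)[1], dim(cube)[2],
         dimnames = list(NULL, dimnames(cube)[[2]]))
}

#' @export
print.ensemble_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("ensemble_cube: %d cells x %d models x %d variables\n",
              d[1], d[2], d[3]))
  cat("models:", paste(dimnames(x)[[2]], collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell between-model standard deviation
#'
#' The heterogeneity of the ensemble's predictions for one variable at
#' every cell: the sample (n-1) standard deviation across models,
#' computed over the models with data at the cell. Cells with fewer
#' than 2 contributing models are masked.
#'
#' @param cube an [ensemble_cube()].
#' @param variable a bioclim variable name, e.g. `"BIO1"`.
#' @return numeric map (one value per cell) with attribute `n_models`
#'   (contributing models per cell).
#' @export
ensemble_sd <- function(cube, variable) {
  stopifnot(inherits(cube, "ensemble_cube"))
  x <- cube_slice(cube, variable)
  n_ok <- rowSums(is.finite(x))
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  out <- ifelse(n_ok >= 2, sqrt(ss / (n_ok - 1)), NA_real_)
  structure(out, n_models = n_ok)
}

#' Per-cell quartile coefficient of dispersion
#'
#' QCD = (q3 - q1) / (q3 + q1) with quartiles taken across models at
#' each cell — a relative measure of ensemble spread. Quartiles use
#' linear interpolation of order statistics (R's default type 7).
#' Variables on a degree-Celsius scale are shifted to Kelvin before the
#' quartiles: the ratio is meaningless around 0 degC and for sub-zero
#' quartiles. Cells with fewer than `min_models` models, or whose
#' shifted `q3 + q1 <= 0`, are masked and counted.
#'
#' @inheritParams ensemble_sd
#' @param shift additive shift applied before the quartiles; the
#'   default (`NULL`) shifts Celsius-scale variables (BIO1, BIO2,
#'   BIO5-BIO11) by +273.15 and leaves the rest unshifted.
#' @param min_models minimum contributing models per cell (default 4).
#' @return numeric map with attributes `shift` and `n_degenerate`
#'   (cells masked by a non-positive denominator).
#' @export
ensemble_qcd <- function(cube, variable, shift = NULL, min_models = 4) {
  stopifnot(inherits(cube, "ensemble_cube"))
  if (is.null(shift)) {
    shift <- if (variable %in% bio_celsius_scale()) 273.15 else 0
  }
  x <- cube_slice(cube, variable) + shift
  n_ok <- rowSums(is.finite(x))
  q <- t(apply(x, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < min_models) return(c(NA_real_, NA_real_))
    quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  }))
  denom <- q[, 1] + q[, 2]
  degenerate <- which(is.finite(denom) & denom <= 0)
  out <- (q[, 2] - q[, 1]) / denom
  out[degenerate] <- NA_real_
  out[n_ok < min_models] <- NA_real_
  structure(out, shift = shift, n_degenerate = length(degenerate))
}

#' All-variable agreement mask
#'
#' A cell agrees when the quartile coefficient of dispersion is below
#' the threshold for every one of the 19 variables defined at that
#' cell; cells where any variable's QCD is masked are undefined.
#'
#' @param qcd_maps named list of 19 aligned QCD maps
#'   (`BIO1`...`BIO19`), as from [ensemble_qcd()].
#' @param threshold agreement threshold (default 0.5).
#' @return integer map: 1 = agree, 0 = disagree, `NA` = undefined.
#' @export
agreement_mask <- function(qcd_maps, threshold = 0.5) {
  missing_vars <- setdiff(bio_names(), names(qcd_maps))
  if (length(missing_vars)) {
    stop("missing QCD maps for: ", paste(missing_vars, collapse = ", "))
  }
  q <- do.call(cbind, qcd_maps[bio_names()])
  agree <- as.integer(rowSums(q < threshold) == 19)
  agree[!complete.cases(q)] <- NA_integer_
  agree
}

#' Latitudinal profile of a map
#'
#' Mean of the unmasked cells in each latitude band, ordered south to
#' north — the latitudinal structure of ensemble disagreement
#' (temperature spread growing poleward, precipitation spread peaking
#' in the tropics).
#'
#' @param map numeric vector in canonical cell order.
#' @param grid the map's [grid_spec()].
#' @param band_width_deg latitude band width in degrees (default 5).
#' @return data.frame with `lat` (band centre), `mean` (`NA` for empty
#'   bands) and `n_cells`, south to north.
#' @export
zonal_profile <- function(map, grid, band_width_deg = 5) {
  stopifnot(inherits(grid, "grid_spec"), length(map) == grid$n_cells)
  lat <- grid_centers(grid)$lat
  edges <- seq(grid$lat_range[1], grid$lat_range[2], by = band_width_deg)
  if (edges[length(edges)] < grid$lat_range[2]) {
    edges <- c(edges, grid$lat_range[2])
  }
  band <- cut(lat, edges, include.lowest = TRUE)
  agg <- tapply(map, band, function(v) {
    c(mean = mean(v, na.rm = TRUE), n = sum(is.finite(v)))
  })
  centre <- (edges[-length(edges)] + edges[-1]) / 2
  means <- vapply(agg, function(a) if (is.null(a)) NA_real_ else a["mean"],
                  numeric(1))
  ns <- vapply(agg, function(a) if (is.null(a)) 0 else a["n"], numeric(1))
  means[ns == 0] <- NA_real_
  data.frame(lat = centre, mean = unname(means), n_cells = unname(ns))
}

#' Regional summary of a map
#'
#' Aggregates a map over a user-supplied labelled region mask (the
#' generic stand-in for named ecoregion polygons): per label, the mean
#' and standard deviation of unmasked cell values and the cell count.
#'
#' @param map numeric vector in canonical cell order.
#' @param region_mask vector of region labels aligned with `map`; `NA`
#'   cells belong to no region.
#' @return data.frame with `region`, `mean`, `sd`, `n_cells` (labels
#'   with zero unmasked cells reported with `n_cells = 0`).
#' @export
region_summary <- function(map, region_mask) {
  stopifnot(length(map) == length(region_mask))
  labels <- sort(unique(region_mask[!is.na(region_mask)]))
  rows <- lapply(labels, function(lb) {
    v <- map[!is.na(region_mask) & region_mask == lb]
    v <- v[is.finite(v)]
    data.frame(region = lb,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else NA_real_,
               n_cells = length(v))
  })
  do.call(rbind, rows)
}
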