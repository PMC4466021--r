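# The 19 bioclimatic variables from 12-month tas, tasmax, tasmin and pr
# layers, following the standard worldclim-lineage definitions, with the
# one deviation that BIO1 is the annual mean of the raw tas variable
# (not the midpoint of tasmax and tasmin).

# 12 x 12 window-membership matrix: column s marks the 3 consecutive
# calendar months of the quarter starting at month s (December-January
# wrap-around allowed).
quarter_window_matrix <- function() {
  W <- matrix(0, 12, 12)
  for (s in 1:12) W[(s - 1 + 0:2) %% 12 + 1, s] <- 1
  W
}

#' Select the extremal 3-month quarter
#'
#' Evaluates all 12 wrap-around windows of 3 consecutive calendar
#' months. Wettest/driest quarters maximize/minimize the window
#' precipitation sum; warmest/coldest quarters maximize/minimize the
#' window mean temperature. Ties are broken by the earliest start
#' month.
#'
#' @param values numeric vector of 12 monthly values (precipitation for
#'   wettest/driest, temperature for warmest/coldest), or an
#'   `n x 12` matrix for many cells at once.
#' @param criterion one of `"wettest"`, `"driest"`, `"warmest"`,
#'   `"coldest"`.
#' @return integer start month(s) of the selected quarter (1-12); `NA`
#'   where any monthly value is non-finite.
#' @examples
#' select_quarter(1:12, "wettest")  # quarter Oct-Dec (starts month 10)
#' @export
select_quarter <- function(values,
                           criterion = c("wettest", "driest",
                                         "warmest", "coldest")) {
  criterion <- match.arg(criterion)
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != 12) stop("exactly 12 monthly values are required")
  agg <- values %*% quarter_window_matrix()
  maximize <- criterion %in% c("wettest", "warmest")
  start <- max.col(if (maximize) agg else -agg, ties.method = "first")
  start[!complete.cases(values)] <- NA_integer_
  if (nrow(values) == 1) start[1] else start
}

row_sd <- function(x, sample_sd = TRUE) {
  mu <- rowMeans(x)
  ss <- rowSums((x - mu)^2)
  sqrt(ss / (ncol(x) - if (sample_sd) 1 else 0))
}

#' Compute the 19 bioclimatic variables
#'
#' Derives BIO1-BIO19 from aligned 12-month mean/maximum/minimum
#' temperature (degC) and precipitation (mm/month) fields:
#' annual summaries (BIO1, BIO12), variability (BIO2, BIO3, BIO4,
#' BIO7, BIO15), monthly extremes (BIO5, BIO6, BIO13, BIO14) and
#' quarter aggregates over the wettest/driest/warmest/coldest quarters
#' (BIO8-BIO11, BIO16-BIO19). BIO1 is the annual mean of the raw `tas`
#' variable. BIO4 is 100 x the standard deviation of monthly `tas`
#' (sample, n-1); BIO15 is 100 x sd(pr) / (1 + mean(pr)), the +1 mm
#' offset guarding against division by zero in rain-free cells. BIO3 is
#' masked where the annual temperature range BIO7 is zero. Cells with
#' any non-finite input month are masked throughout.
#'
#' @param tas,tasmax,tasmin,pr aligned [monthly_field()]s in degC and
#'   mm/month.
#' @param sample_sd use the n-1 denominator in BIO4 and BIO15 (default
#'   `TRUE`); `FALSE` gives the population form.
#' @param bio15_offset include the +1 mm offset in the BIO15 denominator
#'   (default `TRUE`).
#' @return an object of class `bioclim_stack`: an `n_cells x 19` matrix
#'   with columns `BIO1`...`BIO19` and attributes `grid`, `model_id`,
#'   `scenario`, `sample_sd`, `bio15_offset`.
#' @export
compute_bioclim <- function(tas, tasmax, tasmin, pr, sample_sd = TRUE,
                            bio15_offset = TRUE) {
  fields <- list(tas = tas, tasmax = tasmax, tasmin = tasmin, pr = pr)
  for (f in fields) stopifnot(inherits(f, "monthly_climate_field"))
  for (f in fields[-1]) {
    if (!same_grid(tas$grid, f$grid)) stop("input grids are not aligned")
  }
  for (v in c("tas", "tasmax", "tasmin")) {
    if (fields[[v]]$units != "degC") {
      stop(v, " must be in degC, got '", fields[[v]]$units, "'")
    }
  }
  if (pr$units != "mm/month") {
    stop("pr must be in mm/month, got '", pr$units, "'")
  }

  Ta <- tas$values; Tx <- tasmax$values; Tn <- tasmin$values
  P <- pr$values
  n <- nrow(Ta)
  masked <- !(complete.cases(Ta) & complete.cases(Tx) &
                complete.cases(Tn) & complete.cases(P))

  W <- quarter_window_matrix()
  tas_q <- (Ta %*% W) / 3   # quarter mean temperatures
  pr_q <- P %*% W           # quarter precipitation sums

  pick <- function(mat, start) mat[cbind(seq_len(n), start)]
  st <- list(
    wet = max.col(pr_q, ties.method = "first"),
    dry = max.col(-pr_q, ties.method = "first"),
    warm = max.col(tas_q, ties.method = "first"),
    cold = max.col(-tas_q, ties.method = "first"))

  out <- matrix(NA_real_, n, 19, dimnames = list(NULL, bio_names()))
  out[, "BIO1"] <- rowMeans(Ta)
  out[, "BIO2"] <- rowMeans(Tx - Tn)
  out[, "BIO4"] <- 100 * row_sd(Ta, sample_sd)
  out[, "BIO5"] <- apply(Tx, 1, max)
  out[, "BIO6"] <- apply(Tn, 1, min)
  out[, "BIO7"] <- out[, "BIO5"] - out[, "BIO6"]
  out[, "BIO3"] <- ifelse(out[, "BIO7"] == 0, NA_real_,
                          100 * out[, "BIO2"] / out[, "BIO7"])
  out[, "BIO8"] <- pick(tas_q, st$wet)
  out[, "BIO9"] <- pick(tas_q, st$dry)
  out[, "BIO10"] <- pick(tas_q, st$warm)
  out[, "BIO11"] <- pick(tas_q, st$cold)
  out[, "BIO12"] <- rowSums(P)
  out[, "BIO13"] <- apply(P, 1, max)
  out[, "BIO14"] <- apply(P, 1, min)
  out[, "BIO15"] <- 100 * row_sd(P, sample_sd) /
    (rowMeans(P) + if (bio15_offset) 1 else 0)
  out[, "BIO16"] <- pick(pr_q, st$wet)
  out[, "BIO17"] <- pick(pr_q, st$dry)
  out[, "BIO18"] <- pick(pr_q, st$warm)
  out[, "BIO19"] <- pick(pr_q, st$cold)
  out[masked, ] <- NA_real_

  structure(out, grid = tas$grid, model_id = tas$model_id,
            scenario = tas$scenario, sample_sd = sample_sd,
            bio15_offset = bio15_offset,
            class = c("bioclim_stack", "matrix", "array"))
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: %s/%s, %d cells x 19 variables\n",
              attr(x, "model_id"), attr(x, "scenario"), nrow(x)))
  invisible(x)
}
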