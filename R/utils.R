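# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user code.
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Pairwise distances between two point sets, in degrees (Euclidean on
# lon/lat, the convention of the unprojected-coordinate toolchain this
# package mirrors) or great-circle kilometres.
point_distances <- function(lon1, lat1, lon2, lat2,
                            metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    sqrt(outer(lon1, lon2, "-")^2 + outer(lat1, lat2, "-")^2)
  } else {
    hav <- function(x) sin(x / 2)^2
    r1 <- pi / 180
    dphi <- outer(lat1, lat2, "-") * r1
    dlam <- outer(lon1, lon2, "-") * r1
    a <- hav(dphi) + outer(cos(lat1 * r1), cos(lat2 * r1)) * hav(dlam)
    2 * 6371 * asin(pmin(1, sqrt(a)))
  }
}

#' Bioclim variable names and families
#'
#' `bio_names()` returns the 19 standard bioclimatic variable names
#' (`"BIO1"`...`"BIO19"`). `bio_family()` maps each to its family:
#' BIO1-BIO11 are temperature variables, BIO12-BIO19 precipitation
#' variables.
#'
#' @param variable character vector of variable names such as `"BIO4"`.
#' @return `bio_names()`: character vector of length 19. `bio_family()`:
#'   character vector of `"temperature"` / `"precipitation"`.
#' @export
bio_names <- function() paste0("BIO", 1:19)

#' @rdname bio_names
#' @export
bio_family <- function(variable) {
  idx <- match(variable, bio_names())
  if (anyNA(idx)) {
    stop("unknown bioclim variable: ",
         paste(variable[is.na(idx)], collapse = ", "))
  }
  ifelse(idx <= 11, "temperature", "precipitation")
}

# Variables on a degree-Celsius scale; the quartile coefficient of
# dispersion shifts these to Kelvin before taking quartiles.
bio_celsius_scale <- function() paste0("BIO", c(1, 2, 5, 6, 7, 8, 9, 10, 11))
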