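# Independent brute-force oracles used to verify the fast
# implementations; each follows the defining formula by explicit loops
# or dense linear algebra, never the package's own code path.

# Dense ordinary-kriging solve using ALL observations: build the full
# (n+1) system with the Lagrange multiplier and solve it directly.
dense_krige_oracle <- function(lon, lat, z, model, tlon, tlat) {
  n <- length(z)
  d <- sqrt(outer(lon, lon, "-")^2 + outer(lat, lat, "-")^2)
  G <- vgm_gamma(model, d)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  vapply(seq_along(tlon), function(t) {
    d0 <- sqrt((lon - tlon[t])^2 + (lat - tlat[t])^2)
    w <- solve(A, c(vgm_gamma(model, d0), 1))
    sum(w[1:n] * z)
  }, numeric(1))
}

# Pairwise semivariance in one distance band, by exhaustive loop.
semivariance_band_oracle <- function(lon, lat, z, d_lo, d_hi) {
  acc <- 0
  np <- 0L
  n <- length(z)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2)
      if (d > d_lo && d <= d_hi) {
        acc <- acc + 0.5 * (z[i] - z[j])^2
        np <- np + 1L
      }
    }
  }
  c(gamma = acc / np, np = np)
}

# Quarter start month by exhaustive evaluation of the 12 wrap-around
# windows; maximize = TRUE picks the largest aggregate, ties going to
# the earliest start.
quarter_oracle <- function(values, maximize, use_mean = FALSE) {
  best <- NA_integer_
  best_val <- if (maximize) -Inf else Inf
  for (s in 1:12) {
    months <- ((s - 1 + 0:2) %% 12) + 1
    agg <- sum(values[months])
    if (use_mean) agg <- agg / 3
    better <- if (maximize) agg > best_val else agg < best_val
    if (better) {
      best <- s
      best_val <- agg
    }
  }
  best
}

# All 19 bioclim values for one cell, straight from the definitions with
# explicit loops.
bioclim_oracle <- function(tas, tasmax, tasmin, pr) {
  sdev <- function(x) {
    m <- sum(x) / 12
    sqrt(sum((x - m)^2) / 11)
  }
  qsum <- function(x, s) sum(x[((s - 1 + 0:2) %% 12) + 1])
  wet <- quarter_oracle(pr, TRUE)
  dry <- quarter_oracle(pr, FALSE)
  warm <- quarter_oracle(tas, TRUE, use_mean = TRUE)
  cold <- quarter_oracle(tas, FALSE, use_mean = TRUE)
  b <- numeric(19)
  b[1] <- sum(tas) / 12
  b[2] <- sum(tasmax - tasmin) / 12
  b[4] <- 100 * sdev(tas)
  b[5] <- max(tasmax)
  b[6] <- min(tasmin)
  b[7] <- b[5] - b[6]
  b[3] <- if (b[7] == 0) NA_real_ else 100 * b[2] / b[7]
  b[8] <- qsum(tas, wet) / 3
  b[9] <- qsum(tas, dry) / 3
  b[10] <- qsum(tas, warm) / 3
  b[11] <- qsum(tas, cold) / 3
  b[12] <- sum(pr)
  b[13] <- max(pr)
  b[14] <- min(pr)
  b[15] <- 100 * sdev(pr) / (1 + sum(pr) / 12)
  b[16] <- qsum(pr, wet)
  b[17] <- qsum(pr, dry)
  b[18] <- qsum(pr, warm)
  b[19] <- qsum(pr, cold)
  names(b) <- paste0("BIO", 1:19)
  b
}

# Type-7 quantile by manual order-statistic interpolation.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}
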