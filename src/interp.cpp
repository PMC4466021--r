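// Inner loops for neighbourhood interpolation and sample variograms.
// Distances are Euclidean in degrees on (lon, lat) by default, matching
// the unprojected-coordinate convention of the surrounding R code; an
// optional great-circle (haversine, km) metric is supported.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double EARTH_R = 6371.0;

static inline double dist2_euclid(double x1, double y1, double x2, double y2) {
  double dx = x1 - x2, dy = y1 - y2;
  return dx * dx + dy * dy;
}

static inline double dist_haversine(double lon1, double lat1,
                                    double lon2, double lat2) {
  const double r = M_PI / 180.0;
  double dphi = (lat1 - lat2) * r, dlam = (lon1 - lon2) * r;
  double a = std::sin(dphi / 2) * std::sin(dphi / 2) +
             std::cos(lat1 * r) * std::cos(lat2 * r) *
             std::sin(dlam / 2) * std::sin(dlam / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// Spherical semivariance: 0 at h = 0, nugget + psill * (1.5u - 0.5u^3)
// for 0 < h < range, nugget + psill beyond the range.
static inline double sph_gamma(double h, double nugget, double psill,
                               double range) {
  if (h <= 0.0) return 0.0;
  if (h >= range) return nugget + psill;
  double u = h / range;
  return nugget + psill * (1.5 * u - 0.5 * u * u * u);
}

// Omnidirectional binned sample variogram by exhaustive pair scan.
// breaks: ascending bin edges; pairs with distance in (breaks[j],
// breaks[j+1]] contribute to bin j. Returns per-bin pair counts, mean
// distances and mean semivariances.
// [[Rcpp::export]]
List cpp_semivariance_bins(NumericVector x, NumericVector y, NumericVector z,
                           NumericVector breaks, bool haversine) {
  int n = x.size();
  int nb = breaks.size() - 1;
  NumericVector gsum(nb), dsum(nb);
  IntegerVector np(nb);
  double maxd = breaks[nb];
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = haversine
        ? dist_haversine(x[i], y[i], x[j], y[j])
        : std::sqrt(dist2_euclid(x[i], y[i], x[j], y[j]));
      if (d <= breaks[0] || d > maxd) continue;
      // linear scan is fine: nb is small (typically 15)
      int b = 0;
      while (b < nb - 1 && d > breaks[b + 1]) ++b;
      double dz = z[i] - z[j];
      gsum[b] += 0.5 * dz * dz;
      dsum[b] += d;
      np[b] += 1;
    }
  }
  NumericVector gamma(nb), dist(nb);
  for (int b = 0; b < nb; ++b) {
    gamma[b] = np[b] > 0 ? gsum[b] / np[b] : NA_REAL;
    dist[b] = np[b] > 0 ? dsum[b] / np[b] : NA_REAL;
  }
  return List::create(_["dist"] = dist, _["gamma"] = gamma, _["np"] = np);
}

// k nearest observations of (tx, ty) among (ox, oy); ties in distance
// keep the earlier observation index (callers pre-sort observations by
// (lat, lon) for a deterministic order).
static void knn_select(const NumericVector& ox, const NumericVector& oy,
                       double tx, double ty, int k, bool haversine,
                       std::vector<int>& idx, std::vector<double>& dist) {
  int n = ox.size();
  idx.clear(); dist.clear();
  // insertion into a small sorted buffer; strict < keeps earlier indices
  for (int i = 0; i < n; ++i) {
    double d = haversine
      ? dist_haversine(ox[i], oy[i], tx, ty)
      : dist2_euclid(ox[i], oy[i], tx, ty);
    if ((int)idx.size() < k) {
      int p = idx.size();
      idx.push_back(i); dist.push_back(d);
      while (p > 0 && dist[p] < dist[p - 1]) {
        std::swap(dist[p], dist[p - 1]);
        std::swap(idx[p], idx[p - 1]);
        --p;
      }
    } else if (d < dist[k - 1]) {
      dist[k - 1] = d; idx[k - 1] = i;
      int p = k - 1;
      while (p > 0 && dist[p] < dist[p - 1]) {
        std::swap(dist[p], dist[p - 1]);
        std::swap(idx[p], idx[p - 1]);
        --p;
      }
    }
  }
  if (!haversine) {
    for (size_t p = 0; p < dist.size(); ++p) dist[p] = std::sqrt(dist[p]);
  }
}

// Ordinary kriging / inverse-distance interpolation from the k nearest
// observations at each target point.
//   method 0: ordinary kriging with the spherical variogram
//             (nugget, psill, range); solves the (k+1) system with the
//             Lagrange multiplier enforcing sum(lambda) = 1.
//   method 1: IDW with the given power; an exact hit (distance 0)
//             returns the observation.
// Returns predictions, the sum of kriging weights at each target (1 by
// construction; returned for verification) and the count of targets
// masked by a singular system.
// [[Rcpp::export]]
List cpp_knn_interp(NumericVector ox, NumericVector oy, NumericVector oz,
                    NumericVector tx, NumericVector ty,
                    int k, int method,
                    double nugget, double psill, double range,
                    double power, bool haversine) {
  int nt = tx.size();
  int n = ox.size();
  if (k > n) k = n;
  NumericVector pred(nt), wsum(nt);
  int n_singular = 0;
  std::vector<int> idx;
  std::vector<double> dist;
  bool degenerate = (nugget + psill) < 1e-12;  // flat variogram: all obs alike

  arma::mat A(k + 1, k + 1);
  arma::vec b(k + 1), w(k + 1);

  for (int t = 0; t < nt; ++t) {
    knn_select(ox, oy, tx[t], ty[t], k, haversine, idx, dist);

    if (method == 1) {  // IDW
      if (dist[0] <= 0.0) {
        pred[t] = oz[idx[0]];
        wsum[t] = 1.0;
        continue;
      }
      double s = 0.0, sw = 0.0;
      for (int i = 0; i < k; ++i) {
        double wi = 1.0 / std::pow(dist[i], power);
        s += wi * oz[idx[i]];
        sw += wi;
      }
      pred[t] = s / sw;
      wsum[t] = 1.0;
      continue;
    }

    if (degenerate) {  // zero total sill: simple neighbourhood mean
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += oz[idx[i]];
      pred[t] = s / k;
      wsum[t] = 1.0;
      continue;
    }

    for (int i = 0; i < k; ++i) {
      A(i, i) = 0.0;
      for (int j = i + 1; j < k; ++j) {
        double d = haversine
          ? dist_haversine(ox[idx[i]], oy[idx[i]], ox[idx[j]], oy[idx[j]])
          : std::sqrt(dist2_euclid(ox[idx[i]], oy[idx[i]],
                                   ox[idx[j]], oy[idx[j]]));
        double g = sph_gamma(d, nugget, psill, range);
        A(i, j) = g;
        A(j, i) = g;
      }
      A(i, k) = 1.0;
      A(k, i) = 1.0;
      b[i] = sph_gamma(dist[i], nugget, psill, range);
    }
    A(k, k) = 0.0;
    b[k] = 1.0;

    bool ok = arma::solve(w, A, b,
                          arma::solve_opts::no_approx + arma::solve_opts::fast);
    if (!ok || !w.is_finite()) {
      pred[t] = NA_REAL;
      wsum[t] = NA_REAL;
      ++n_singular;
      continue;
    }
    double s = 0.0, sw = 0.0;
    for (int i = 0; i < k; ++i) {
      s += w[i] * oz[idx[i]];
      sw += w[i];
    }
    pred[t] = s;
    wsum[t] = sw;
  }
  return List::create(_["pred"] = pred, _["wsum"] = wsum,
                      _["n_singular"] = n_singular);
}
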