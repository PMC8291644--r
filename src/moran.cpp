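// Streamed Moran's I: spatial weights are recomputed from coordinates in
// row blocks so the n x n matrix is never materialized. Peak auxiliary
// memory is O(block_size * n) (the block buffer) plus O(n) row bookkeeping.
//
// Distances are great-circle km on the mean-radius sphere. For speed the
// kernel works in squared unit-sphere chord space (3-flop dot products);
// the asin() back-transform to km runs only for pairs inside the band,
// and chord ordering equals great-circle ordering, so results are
// identical to a direct haversine implementation up to round-off.
//
// Schemes (scheme code):
//   0 inverse_distance: a_ij = 1 / max(d_ij, min_dist_km), zero beyond
//     cutoff_km
//   1 k_nearest: a_ij = 1 for the k nearest neighbours of i (ties broken
//     by lower index)
//   2 distance_band: a_ij = 1 for 0 <= d_ij <= cutoff_km, j != i
// Row standardization divides each row by its sum (rows with no
// neighbours stay zero).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double EARTH_R = 6371.0088;

struct Geo {
  std::vector<double> x, y, zc;
  explicit Geo(const NumericVector& lat, const NumericVector& lon) {
    int n = lat.size();
    x.resize(n); y.resize(n); zc.resize(n);
    for (int i = 0; i < n; ++i) {
      double phi = lat[i] * M_PI / 180.0, lam = lon[i] * M_PI / 180.0;
      x[i] = std::cos(phi) * std::cos(lam);
      y[i] = std::cos(phi) * std::sin(lam);
      zc[i] = std::sin(phi);
    }
  }
  // squared unit-sphere chord distance (monotone in great-circle
  // distance); computed from coordinate differences, not 2 - 2*dot, to
  // avoid cancellation for nearby points
  inline double chordsq(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = zc[i] - zc[j];
    return dx * dx + dy * dy + dz * dz;
  }
};

// great-circle km from squared chord
static inline double chordsq_to_km(double c2) {
  double h = 0.5 * std::sqrt(c2);
  if (h > 1.0) h = 1.0;
  return 2.0 * EARTH_R * std::asin(h);
}

// squared chord corresponding to a km cutoff
static inline double km_to_chordsq(double km) {
  double a = km / (2.0 * EARTH_R);
  if (a > M_PI_2) return 4.0;
  double s = 2.0 * std::sin(a);
  return s * s;
}

// kNN threshold per row: (chordsq, index) of the k-th nearest neighbour
// under lexicographic order.
static void knn_thresholds(const Geo& geo, int n, int k,
                           std::vector<double>& kd, std::vector<int>& kidx) {
  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    cand.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand.push_back(std::make_pair(geo.chordsq(i, j), j));
    }
    std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
    kd[i] = cand[k - 1].first;
    kidx[i] = cand[k - 1].second;
  }
}

inline bool in_knn(double c2, int j, double kd, int kidx) {
  return (c2 < kd) || (c2 == kd && j <= kidx);
}

// [[Rcpp::export]]
List moran_stream_cpp(NumericVector z, NumericVector lat, NumericVector lon,
                      int scheme, double cutoff_km, int k, bool row_std,
                      double min_dist_km, int block_size) {
  int n = z.size();
  if (lat.size() != n || lon.size() != n) stop("coordinate length mismatch");
  if (n < 3) stop("need at least 3 observations");
  if (block_size < 1) block_size = 1;
  Geo geo(lat, lon);
  double cut2 = km_to_chordsq(cutoff_km);

  std::vector<double> kd; std::vector<int> kidx;
  std::vector<double> rowsum(n, 0.0);
  std::vector<double> cbuf((size_t)block_size * n);

  // pass 1: raw row sums (and kNN thresholds)
  if (scheme == 1) {
    if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
    kd.resize(n); kidx.resize(n);
    knn_thresholds(geo, n, k, kd, kidx);
    for (int i = 0; i < n; ++i) rowsum[i] = (double)k;
  } else {
    for (int i0 = 0; i0 < n; i0 += block_size) {
      int iend = std::min(i0 + block_size, n);
      for (int i = i0; i < iend; ++i) {
        double* crow = &cbuf[(size_t)(i - i0) * n];
        double rs = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double c2 = geo.chordsq(i, j);
          crow[j] = c2;
          if (c2 <= cut2) {
            rs += (scheme == 0)
              ? 1.0 / std::max(chordsq_to_km(c2), min_dist_km) : 1.0;
          }
        }
        rowsum[i] = rs;
      }
    }
  }

  // pass 2: recompute each block's chord distances and accumulate
  // num = sum w_ij z_i z_j, S0, S1 (one (w_ij + w_ji)^2 per unordered
  // pair = half the ordered double sum), and row/column weight sums
  double num = 0.0, S0 = 0.0, S1 = 0.0;
  std::vector<double> colsum(n, 0.0), wrowsum(n, 0.0);
  for (int i0 = 0; i0 < n; i0 += block_size) {
    int iend = std::min(i0 + block_size, n);
    for (int i = i0; i < iend; ++i) {
      double* crow = &cbuf[(size_t)(i - i0) * n];
      for (int j = 0; j < n; ++j) {
        if (j != i) crow[j] = geo.chordsq(i, j);
      }
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double c2 = crow[j];
        double aij, aji;
        if (scheme == 1) {
          aij = in_knn(c2, j, kd[i], kidx[i]) ? 1.0 : 0.0;
          aji = in_knn(c2, i, kd[j], kidx[j]) ? 1.0 : 0.0;
        } else if (scheme == 0) {
          aij = aji = (c2 <= cut2)
            ? 1.0 / std::max(chordsq_to_km(c2), min_dist_km) : 0.0;
        } else {
          aij = aji = (c2 <= cut2) ? 1.0 : 0.0;
        }
        double wij = aij, wji = aji;
        if (row_std) {
          wij = (rowsum[i] > 0) ? aij / rowsum[i] : 0.0;
          wji = (rowsum[j] > 0) ? aji / rowsum[j] : 0.0;
        }
        if (wij != 0.0) {
          num += wij * z[i] * z[j];
          S0 += wij;
          wrowsum[i] += wij;
          colsum[j] += wij;
        }
        if (j > i) {
          double s = wij + wji;
          S1 += s * s;
        }
      }
    }
  }
  double S2 = 0.0;
  for (int i = 0; i < n; ++i) {
    double t = wrowsum[i] + colsum[i];
    S2 += t * t;
  }
  return List::create(_["num"] = num, _["S0"] = S0, _["S1"] = S1,
                      _["S2"] = S2);
}

// Numerator sum_ij w_ij z_i z_j for each column of Z (permutation tests);
// weights recomputed on the fly once per row.
// [[Rcpp::export]]
NumericVector moran_num_multi_cpp(NumericMatrix Z, NumericVector lat,
                                  NumericVector lon, int scheme,
                                  double cutoff_km, int k, bool row_std,
                                  double min_dist_km) {
  int n = Z.nrow(), B = Z.ncol();
  Geo geo(lat, lon);
  double cut2 = km_to_chordsq(cutoff_km);
  std::vector<double> kd; std::vector<int> kidx;
  std::vector<double> rowsum(n, 0.0);
  if (scheme == 1) {
    if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
    kd.resize(n); kidx.resize(n);
    knn_thresholds(geo, n, k, kd, kidx);
    for (int i = 0; i < n; ++i) rowsum[i] = (double)k;
  } else {
    for (int i = 0; i < n; ++i) {
      double rs = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double c2 = geo.chordsq(i, j);
        if (c2 <= cut2) {
          rs += (scheme == 0)
            ? 1.0 / std::max(chordsq_to_km(c2), min_dist_km) : 1.0;
        }
      }
      rowsum[i] = rs;
    }
  }
  NumericVector out(B);
  std::vector<int> nz_j; std::vector<double> nz_w;
  for (int i = 0; i < n; ++i) {
    nz_j.clear(); nz_w.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double c2 = geo.chordsq(i, j);
      double aij;
      if (scheme == 1) {
        aij = in_knn(c2, j, kd[i], kidx[i]) ? 1.0 : 0.0;
      } else if (scheme == 0) {
        aij = (c2 <= cut2)
          ? 1.0 / std::max(chordsq_to_km(c2), min_dist_km) : 0.0;
      } else {
        aij = (c2 <= cut2) ? 1.0 : 0.0;
      }
      if (aij == 0.0) continue;
      double wij = row_std ? ((rowsum[i] > 0) ? aij / rowsum[i] : 0.0) : aij;
      if (wij != 0.0) { nz_j.push_back(j); nz_w.push_back(wij); }
    }
    int m = (int)nz_j.size();
    for (int b = 0; b < B; ++b) {
      const double* zb = &Z(0, b);
      double acc = 0.0;
      for (int t = 0; t < m; ++t) acc += nz_w[t] * zb[nz_j[t]];
      out[b] += zb[i] * acc;
    }
  }
  return out;
}
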