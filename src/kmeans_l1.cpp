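#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Lloyd iterations for k-means under the Manhattan (L1) metric: assignment
// minimizes L1 distance (ties to the lowest center index), the centroid
// update is the coordinate-wise median (lower/upper-middle average for even
// counts, matching stats::median). An emptied cluster is re-seeded at the
// point farthest (L1) from its currently assigned centroid. Runs each set
// of initial centers passed in and returns the solution with the lowest
// total within-cluster L1 cost. No RNG is used here; all randomness lives
// in the R-side initialization.

// L1 distance with four accumulators to break the FP-add latency chain.
static inline double l1_dist(const double* a, const double* b, int p) {
  double d0 = 0.0, d1 = 0.0, d2 = 0.0, d3 = 0.0;
  int j = 0;
  for (; j + 4 <= p; j += 4) {
    d0 += std::fabs(a[j] - b[j]);
    d1 += std::fabs(a[j + 1] - b[j + 1]);
    d2 += std::fabs(a[j + 2] - b[j + 2]);
    d3 += std::fabs(a[j + 3] - b[j + 3]);
  }
  for (; j < p; ++j) d0 += std::fabs(a[j] - b[j]);
  return (d0 + d1) + (d2 + d3);
}

static double col_median(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double hi = v[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + h);
  return (lo + hi) / 2.0;
}

// [[Rcpp::export]]
List kmeans_l1_run(NumericMatrix x, NumericMatrix init_centers, int k,
                   int max_iter) {
  const int m = x.nrow(), p = x.ncol();
  const int n_init = init_centers.nrow() / k;
  if (init_centers.ncol() != p)
    stop("init_centers must have the same number of columns as x");

  // row-major copy for assignment, column-major for the median update
  std::vector<double> xr((size_t)m * p);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < p; ++j) xr[(size_t)i * p + j] = x(i, j);
  const double* xc = x.begin(); // NumericMatrix is column-major

  std::vector<int> best_lab(m);
  std::vector<double> best_cent((size_t)k * p);
  double best_cost = R_PosInf;
  int best_iter = 0;

  std::vector<double> cent((size_t)k * p), dist_own(m), buf;
  std::vector<int> lab(m, -1), prev(m);
  std::vector<std::vector<int>> members(k);

  for (int r = 0; r < n_init; ++r) {
    for (int c = 0; c < k; ++c)
      for (int j = 0; j < p; ++j)
        cent[(size_t)c * p + j] = init_centers(r * k + c, j);
    std::fill(lab.begin(), lab.end(), -1);
    double cost = 0.0, prev_cost = R_PosInf;
    int iter = 0;
    for (; iter < max_iter; ++iter) {
      prev = lab;
      cost = 0.0;
      // assignment (ties go to the lowest center index)
      for (int i = 0; i < m; ++i) {
        double dmin = R_PosInf;
        int cmin = 0;
        const double* xi = &xr[(size_t)i * p];
        for (int c = 0; c < k; ++c) {
          double d = l1_dist(xi, &cent[(size_t)c * p], p);
          if (d < dmin - 1e-12) { dmin = d; cmin = c; }
        }
        lab[i] = cmin;
        dist_own[i] = dmin;
        cost += dmin;
      }
      // re-seed empty clusters at the point farthest from its centroid
      std::vector<int> cnt(k, 0);
      for (int i = 0; i < m; ++i) cnt[lab[i]]++;
      bool reseeded = false;
      for (int c = 0; c < k; ++c) {
        if (cnt[c] == 0) {
          int far = (int)(std::max_element(dist_own.begin(), dist_own.end()) -
                          dist_own.begin());
          for (int j = 0; j < p; ++j)
            cent[(size_t)c * p + j] = xr[(size_t)far * p + j];
          cnt[lab[far]]--;
          lab[far] = c;
          cnt[c] = 1;
          dist_own[far] = 0.0;
          reseeded = true;
        }
      }
      // stop on label fixed point or cost plateau (tie oscillation)
      if (!reseeded &&
          (lab == prev || prev_cost - cost <= 1e-9 * (1.0 + cost)))
        break;
      prev_cost = cost;
      // centroid update: coordinate-wise median over each cluster's
      // members; coordinates outer so one data column stays cache-resident
      for (int c = 0; c < k; ++c) members[c].clear();
      for (int i = 0; i < m; ++i) members[lab[i]].push_back(i);
      for (int j = 0; j < p; ++j) {
        const double* col = xc + (size_t)j * m;
        for (int c = 0; c < k; ++c) {
          const std::vector<int>& idx = members[c];
          if (idx.empty()) continue;
          buf.clear();
          buf.reserve(idx.size());
          for (int i : idx) buf.push_back(col[i]);
          cent[(size_t)c * p + j] = col_median(buf);
        }
      }
    }
    // final assignment/cost with converged centers
    cost = 0.0;
    for (int i = 0; i < m; ++i) {
      double dmin = R_PosInf;
      int cmin = 0;
      const double* xi = &xr[(size_t)i * p];
      for (int c = 0; c < k; ++c) {
        double d = l1_dist(xi, &cent[(size_t)c * p], p);
        if (d < dmin - 1e-12) { dmin = d; cmin = c; }
      }
      lab[i] = cmin;
      cost += dmin;
    }
    if (cost < best_cost) {
      best_cost = cost;
      best_lab = lab;
      best_cent = cent;
      best_iter = iter + 1;
    }
  }

  IntegerVector labels(m);
  for (int i = 0; i < m; ++i) labels[i] = best_lab[i] + 1;
  NumericMatrix centers(k, p);
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) centers(c, j) = best_cent[(size_t)c * p + j];
  return List::create(_["labels"] = labels, _["centers"] = centers,
                      _["cost"] = best_cost, _["iterations"] = best_iter);
}

// k-means++-style seeding under L1: the first center of each restart is
// picked uniformly, subsequent ones with probability proportional to the
// L1 distance to the nearest chosen center. All randomness comes from the
// `unif` matrix (k x n_init uniforms drawn in R), so seeding is
// reproducible and RNG-stream identical across platforms.
// [[Rcpp::export]]
NumericMatrix kmeanspp_l1_seed(NumericMatrix x, int k, int n_init,
                               NumericMatrix unif) {
  const int m = x.nrow(), p = x.ncol();
  if (unif.nrow() < k || unif.ncol() < n_init) stop("not enough uniforms");
  std::vector<double> xr((size_t)m * p);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < p; ++j) xr[(size_t)i * p + j] = x(i, j);
  NumericMatrix centers((size_t)k * n_init, p);
  std::vector<double> dmin(m);
  for (int r = 0; r < n_init; ++r) {
    int idx = std::min(m - 1, (int)(unif(0, r) * m));
    for (int j = 0; j < p; ++j) centers(r * k, j) = xr[(size_t)idx * p + j];
    if (k == 1) continue;
    for (int i = 0; i < m; ++i)
      dmin[i] = l1_dist(&xr[(size_t)i * p], &xr[(size_t)idx * p], p);
    for (int c = 1; c < k; ++c) {
      double total = 0.0;
      for (int i = 0; i < m; ++i) total += dmin[i];
      double u = unif(c, r);
      int pick = m - 1;
      if (total > 0) {
        double target = u * total, acc = 0.0;
        for (int i = 0; i < m; ++i) {
          acc += dmin[i];
          if (acc >= target) { pick = i; break; }
        }
      } else {
        pick = std::min(m - 1, (int)(u * m)); // all points coincide
      }
      for (int j = 0; j < p; ++j)
        centers(r * k + c, j) = xr[(size_t)pick * p + j];
      if (c + 1 < k) {
        for (int i = 0; i < m; ++i) {
          double d = l1_dist(&xr[(size_t)i * p], &xr[(size_t)pick * p], p);
          if (d < dmin[i]) dmin[i] = d;
        }
      }
    }
  }
  return centers;
}

// Cityblock cross-distance: rows of a vs rows of b (used for distances to
// centroids in the validity indices).
// [[Rcpp::export]]
NumericMatrix cross_l1(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), p = a.ncol();
  if (b.ncol() != p) stop("column mismatch");
  NumericMatrix d(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int t = 0; t < p; ++t) s += std::fabs(a(i, t) - b(j, t));
      d(i, j) = s;
    }
  return d;
}
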