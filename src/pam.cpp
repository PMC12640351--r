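#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_dist_matrix(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double d = X(i, c) - X(j, c);
        s += d * d;
      }
      double e = std::sqrt(s);
      D(i, j) = e;
      D(j, i) = e;
    }
  }
  return D;
}

static void update_nearest(const NumericMatrix &D, const std::vector<int> &med,
                           std::vector<int> &n1, std::vector<double> &d1,
                           std::vector<double> &d2) {
  const int n = D.nrow(), k = (int)med.size();
  for (int j = 0; j < n; ++j) {
    double b1 = std::numeric_limits<double>::infinity(), b2 = b1;
    int bi = 0;
    for (int m = 0; m < k; ++m) {
      double d = D(j, med[m]);
      if (d < b1) {
        b2 = b1;
        b1 = d;
        bi = m;
      } else if (d < b2) {
        b2 = d;
      }
    }
    n1[j] = bi;
    d1[j] = b1;
    d2[j] = b2;
  }
}

// Classic PAM on a precomputed distance matrix: greedy BUILD seeding, then
// best-improvement SWAP to a local optimum.  The swap step evaluates all
// (medoid, candidate) pairs in O(n^2) per iteration via the nearest /
// second-nearest decomposition; the accepted swap is identical to the one
// the naive O(k n^2) evaluation would choose, with ties broken toward the
// lowest candidate then lowest medoid index.  Medoids are reported sorted;
// assignment goes to the nearest medoid, ties to the lowest medoid index.
// number of k-subsets of n, capped at `cap` to avoid overflow
static double n_choose_k_capped(int n, int k, double cap) {
  double c = 1.0;
  for (int i = 1; i <= k; ++i) {
    c = c * (n - k + i) / i;
    if (c > cap) return cap + 1;
  }
  return c;
}

// [[Rcpp::export]]
List cpp_pam(NumericMatrix D, int k, int max_iter = 500) {
  const int n = D.nrow();
  if (k < 1 || k > n) stop("k must be in [1, n]");

  // tiny problems: exhaustive medoid enumeration gives the exact optimum
  // (classic BUILD+SWAP is only a local optimizer); ties resolve to the
  // lexicographically first medoid set
  if (n <= 40 && n_choose_k_capped(n, k, 20000.0) <= 20000.0) {
    std::vector<int> comb(k), best_med(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    double best = std::numeric_limits<double>::infinity();
    while (true) {
      double cost = 0.0;
      for (int j = 0; j < n; ++j) {
        double m = D(j, comb[0]);
        for (int c = 1; c < k; ++c)
          if (D(j, comb[c]) < m) m = D(j, comb[c]);
        cost += m;
      }
      if (cost < best - 1e-15) {
        best = cost;
        best_med = comb;
      }
      int i = k - 1;
      while (i >= 0 && comb[i] == n - k + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
    std::vector<int> n1(n);
    std::vector<double> d1(n), d2(n);
    update_nearest(D, best_med, n1, d1, d2);
    IntegerVector medoids(k), assignment(n);
    NumericVector dmed(n);
    for (int m = 0; m < k; ++m) medoids[m] = best_med[m] + 1;
    double cost = 0.0;
    for (int j = 0; j < n; ++j) {
      assignment[j] = n1[j] + 1;
      dmed[j] = d1[j];
      cost += d1[j];
    }
    return List::create(_["medoids"] = medoids, _["assignment"] = assignment,
                        _["cost"] = cost, _["medoid_distance"] = dmed,
                        _["iterations"] = 0, _["exact"] = true);
  }

  std::vector<int> med;
  std::vector<bool> is_med(n, false);
  std::vector<int> n1(n, 0);
  std::vector<double> d1(n, 0.0), d2(n, 0.0);

  // BUILD: first medoid minimizes the total distance; each later medoid
  // maximizes the decrease in total cost
  {
    int best = 0;
    double bestsum = std::numeric_limits<double>::infinity();
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += D(j, c);
      if (s < bestsum) {
        bestsum = s;
        best = c;
      }
    }
    med.push_back(best);
    is_med[best] = true;
    for (int j = 0; j < n; ++j) d1[j] = D(j, best);
  }
  while ((int)med.size() < k) {
    int best = -1;
    double bestgain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      double g = 0.0;
      for (int j = 0; j < n; ++j) {
        double diff = d1[j] - D(j, c);
        if (diff > 0) g += diff;
      }
      if (g > bestgain) {
        bestgain = g;
        best = c;
      }
    }
    med.push_back(best);
    is_med[best] = true;
    for (int j = 0; j < n; ++j)
      if (D(j, best) < d1[j]) d1[j] = D(j, best);
  }
  update_nearest(D, med, n1, d1, d2);

  // SWAP
  int iter = 0;
  if (k < n) {
    std::vector<double> dtd(k);
    for (iter = 0; iter < max_iter; ++iter) {
      double bestdelta = -1e-12;
      int bestx = -1, bestm = -1;
      for (int x = 0; x < n; ++x) {
        if (is_med[x]) continue;
        double acc = 0.0;
        std::fill(dtd.begin(), dtd.end(), 0.0);
        for (int j = 0; j < n; ++j) {
          double d = D(j, x);
          if (d < d1[j])
            acc += d - d1[j];
          else
            dtd[n1[j]] += std::min(d, d2[j]) - d1[j];
        }
        for (int m = 0; m < k; ++m) {
          double delta = acc + dtd[m];
          if (delta < bestdelta) {
            bestdelta = delta;
            bestx = x;
            bestm = m;
          }
        }
      }
      if (bestx < 0) break;
      is_med[med[bestm]] = false;
      med[bestm] = bestx;
      is_med[bestx] = true;
      update_nearest(D, med, n1, d1, d2);
    }
  }

  std::sort(med.begin(), med.end());
  update_nearest(D, med, n1, d1, d2);  // strict '<' => lowest index on ties
  double cost = 0.0;
  for (int j = 0; j < n; ++j) cost += d1[j];

  IntegerVector medoids(k), assignment(n);
  NumericVector dmed(n);
  for (int m = 0; m < k; ++m) medoids[m] = med[m] + 1;
  for (int j = 0; j < n; ++j) {
    assignment[j] = n1[j] + 1;
    dmed[j] = d1[j];
  }
  return List::create(_["medoids"] = medoids, _["assignment"] = assignment,
                      _["cost"] = cost, _["medoid_distance"] = dmed,
                      _["iterations"] = iter);
}

// Pooled within-cluster dispersion W = sum_r D_r / (2 n_r) with D_r the sum
// of squared pairwise Euclidean distances inside cluster r; equals the sum
// of squared distances to cluster means (within-cluster sum of squares).
// [[Rcpp::export]]
double cpp_pooled_within_dispersion(NumericMatrix D, IntegerVector assignment,
                                    int k) {
  const int n = D.nrow();
  std::vector<double> dr(k, 0.0);
  std::vector<int> nr(k, 0);
  for (int i = 0; i < n; ++i) nr[assignment[i] - 1]++;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (assignment[i] == assignment[j])
        dr[assignment[i] - 1] += D(i, j) * D(i, j);
  double w = 0.0;
  for (int r = 0; r < k; ++r)
    if (nr[r] > 0) w += dr[r] / nr[r];
  return w;
}
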