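#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-block walk + kernel engine for the lattice transform.
//
// raw  : signal values (length n >= 19)
// norm : normalized values, integers 1..100, same length
// pr   : probability of each normalized value, length 100
// child: adjacency as a list of integer vectors, child[v] = children of
//        vertex v+1, 1-based ids, sorted ascending
// tr   : ternary threshold (half the population sd of `raw`)
//
// Returns an integer matrix (n - 18) x 6 of map-signal values (0..255),
// category order: (min,signum) (max,signum) (min,upper) (min,lower)
// (max,upper) (max,lower).
// [[Rcpp::export]]
IntegerMatrix cpp_lattice_maps(NumericVector raw, IntegerVector norm,
                               NumericVector pr, List child, double tr) {
  const int n = raw.size();
  const int nv = child.size();
  if (norm.size() != n) stop("raw and norm lengths differ");
  if (n < nv) stop("signal shorter than one block");
  const int nblocks = n - nv + 1;

  std::vector<std::vector<int>> ch(nv);
  for (int v = 0; v < nv; ++v) {
    IntegerVector cv = child[v];
    ch[v].assign(cv.begin(), cv.end());
  }
  const int ntier_steps = 8; // 9-vertex paths

  IntegerMatrix maps(nblocks, 6);
  std::vector<double> prob(nv);
  std::vector<int> wmin(nv == 19 ? 9 : 9), wmax(9);

  for (int i = 0; i < nblocks; ++i) {
    for (int j = 0; j < nv; ++j) prob[j] = pr[norm[i + j] - 1];

    // greedy walks; ties go to the lowest child id (children sorted, strict
    // comparison keeps the first)
    int cur_min = 1, cur_max = 1;
    wmin[0] = 1; wmax[0] = 1;
    for (int t = 1; t <= ntier_steps; ++t) {
      const std::vector<int>& cmin = ch[cur_min - 1];
      int best = cmin[0];
      for (size_t k = 1; k < cmin.size(); ++k)
        if (prob[cmin[k] - 1] < prob[best - 1]) best = cmin[k];
      cur_min = best; wmin[t] = best;

      const std::vector<int>& cmax = ch[cur_max - 1];
      best = cmax[0];
      for (size_t k = 1; k < cmax.size(); ++k)
        if (prob[cmax[k] - 1] > prob[best - 1]) best = cmax[k];
      cur_max = best; wmax[t] = best;
    }

    int m_min_sig = 0, m_max_sig = 0, m_min_up = 0, m_min_lo = 0,
        m_max_up = 0, m_max_lo = 0;
    for (int t = 0; t < ntier_steps; ++t) {
      double dmin = raw[i + wmin[t] - 1] - raw[i + wmin[t + 1] - 1];
      double dmax = raw[i + wmax[t] - 1] - raw[i + wmax[t + 1] - 1];
      if (dmin >= 0)   m_min_sig |= 1 << t;
      if (dmin >  tr)  m_min_up  |= 1 << t;
      if (dmin < -tr)  m_min_lo  |= 1 << t;
      if (dmax >= 0)   m_max_sig |= 1 << t;
      if (dmax >  tr)  m_max_up  |= 1 << t;
      if (dmax < -tr)  m_max_lo  |= 1 << t;
    }
    maps(i, 0) = m_min_sig; maps(i, 1) = m_max_sig;
    maps(i, 2) = m_min_up;  maps(i, 3) = m_min_lo;
    maps(i, 4) = m_max_up;  maps(i, 5) = m_max_lo;
  }
  return maps;
}

// Objective and gradient of the regularized leave-one-out NCA criterion with
// a diagonal weighted-L1 metric: d_w(i,j) = sum_d w_d^2 |x_id - x_jd|.
// F(w) = (1/n) sum_i p_i - lambda * sum_d w_d^2, p_i = sum_{j in class i} p_ij.
// Xr is the data in row-major layout (row i at Xr[i*d]) for contiguous
// inner loops over features.
static double nca_pass(const std::vector<double>& Xr, int n, int d,
                       const IntegerVector& y,
                       const std::vector<double>& w, double lambda,
                       std::vector<double>* grad) {
  std::vector<double> w2(d);
  for (int k = 0; k < d; ++k) w2[k] = w[k] * w[k];

  // pairwise distances (symmetric)
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    for (int j = i + 1; j < n; ++j) {
      const double* xj = &Xr[(size_t)j * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k)
        s += w2[k] * std::fabs(xi[k] - xj[k]);
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }

  // softmax kernel p_ij, stabilized per row
  std::vector<double> P((size_t)n * n, 0.0), pi(n, 0.0);
  double F = 0.0;
  for (int i = 0; i < n; ++i) {
    double dmin = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (j != i && D[(size_t)i * n + j] < dmin) dmin = D[(size_t)i * n + j];
    double z = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double e = std::exp(-(D[(size_t)i * n + j] - dmin));
      P[(size_t)i * n + j] = e;
      z += e;
    }
    double psame = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      P[(size_t)i * n + j] /= z;
      if (y[j] == y[i]) psame += P[(size_t)i * n + j];
    }
    pi[i] = psame;
    F += psame;
  }
  F /= n;
  for (int k = 0; k < d; ++k) F -= lambda * w2[k];

  if (grad) {
    // c_ij = p_i * p_ij - [y_i == y_j] * p_ij ; accumulate (c_ij + c_ji)|dx|
    std::vector<double>& g = *grad;
    g.assign(d, 0.0);
    for (int i = 0; i < n; ++i) {
      const double* xi = &Xr[(size_t)i * d];
      for (int j = i + 1; j < n; ++j) {
        double pij = P[(size_t)i * n + j], pji = P[(size_t)j * n + i];
        double same = (y[i] == y[j]) ? 1.0 : 0.0;
        double c = (pi[i] - same) * pij + (pi[j] - same) * pji;
        if (c == 0.0) continue;
        const double* xj = &Xr[(size_t)j * d];
        for (int k = 0; k < d; ++k)
          g[k] += c * std::fabs(xi[k] - xj[k]);
      }
    }
    for (int k = 0; k < d; ++k)
      g[k] = 2.0 * w[k] * g[k] / n - 2.0 * lambda * w[k];
  }
  return F;
}

// Batch gradient ascent with an adaptive step; deterministic (w0 = 1).
// [[Rcpp::export]]
List cpp_nca_weights(NumericMatrix X, IntegerVector y, double lambda,
                     int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("labels length mismatch");
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      Xr[(size_t)i * d + k] = X(i, k);
  std::vector<double> w(d, 1.0), g(d), gtry(d);
  std::vector<double> trace;
  double F = nca_pass(Xr, n, d, y, w, lambda, &g);
  trace.push_back(F);
  double alpha = 0.1;
  int used = 1;
  for (int it = 1; it < max_iter; ++it) {
    std::vector<double> wtry(d);
    for (int k = 0; k < d; ++k) wtry[k] = w[k] + alpha * g[k];
    double Ftry = nca_pass(Xr, n, d, y, wtry, lambda, &gtry);
    ++used;
    if (Ftry >= F) {
      bool done = (Ftry - F) < tol * (std::fabs(F) + tol);
      w.swap(wtry); g.swap(gtry);
      F = Ftry;
      trace.push_back(F);
      alpha *= 1.1;
      if (done) break;
    } else {
      alpha *= 0.5;
      if (alpha < 1e-12) break;
    }
  }
  NumericVector weights(d);
  for (int k = 0; k < d; ++k) weights[k] = w[k] * w[k];
  return List::create(_["weights"] = weights,
                      _["objective"] = NumericVector(trace.begin(), trace.end()),
                      _["evaluations"] = used);
}

// Out-of-fold 1NN predictions under a fixed fold assignment, city-block
// distance over the supplied columns. Ties: smallest training row index.
// y and fold are 1-based integer codes.
// [[Rcpp::export]]
IntegerVector cpp_knn1_cv(NumericMatrix X, IntegerVector y, IntegerVector fold) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      Xr[(size_t)i * d + k] = X(i, k);
  IntegerVector pred(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[(size_t)i * d];
    double best = R_PosInf;
    int bestj = -1;
    for (int j = 0; j < n; ++j) {
      if (fold[j] == fold[i]) continue;
      const double* xj = &Xr[(size_t)j * d];
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        s += std::fabs(xi[k] - xj[k]);
        if (s >= best) break;
      }
      if (s < best) { best = s; bestj = j; }
    }
    if (bestj < 0) stop("a fold has no training neighbours");
    pred[i] = y[bestj];
  }
  return pred;
}

// Accuracy of out-of-fold 1NN over nested column prefixes of the ranked
// feature matrix: one accuracy per v in iv..ncol. Distances are accumulated
// column by column so prefix v+1 reuses prefix v.
// [[Rcpp::export]]
NumericVector cpp_prefix_cv_acc(NumericMatrix X, IntegerVector y,
                                IntegerVector fold, int iv) {
  const int n = X.nrow(), fv = X.ncol();
  if (iv < 1 || iv > fv) stop("invalid iv");
  std::vector<double> D((size_t)n * n, 0.0);
  NumericVector acc(fv - iv + 1);

  for (int v = 1; v <= fv; ++v) {
    for (int i = 0; i < n; ++i) {
      const double xi = X(i, v - 1);
      for (int j = i + 1; j < n; ++j) {
        double a = std::fabs(xi - X(j, v - 1));
        D[(size_t)i * n + j] += a;
        D[(size_t)j * n + i] += a;
      }
    }
    if (v < iv) continue;
    int correct = 0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bestj = -1;
      const size_t off = (size_t)i * n;
      for (int j = 0; j < n; ++j) {
        if (fold[j] == fold[i]) continue;
        if (D[off + j] < best) { best = D[off + j]; bestj = j; }
      }
      if (bestj >= 0 && y[bestj] == y[i]) ++correct;
    }
    acc[v - iv] = (double)correct / n;
  }
  return acc;
}
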