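#include <Rcpp.h>
#include <queue>
#include <utility>
#include <algorithm>
using namespace Rcpp;

// Coordinate descent for the graphical-lasso column subproblem:
//   min_b  (1/2) b' W11 b - s12' b + rho * ||b||_1
// W11 is (M-1)x(M-1) symmetric positive definite, s12 the off-diagonal
// column of the input covariance. Returns the minimizer; beta is warm-started.
// [[Rcpp::export(name = ".lasso_cd")]]
NumericVector lasso_cd(NumericMatrix W11, NumericVector s12, double rho,
                       NumericVector beta0, double tol = 1e-8,
                       int maxit = 1000) {
  int p = s12.size();
  NumericVector beta = clone(beta0);
  // residual r = s12 - W11 %*% beta, maintained incrementally
  NumericVector r(p);
  for (int k = 0; k < p; ++k) {
    double acc = s12[k];
    for (int l = 0; l < p; ++l) acc -= W11(k, l) * beta[l];
    r[k] = acc;
  }
  for (int it = 0; it < maxit; ++it) {
    double maxdiff = 0.0;
    for (int k = 0; k < p; ++k) {
      double old = beta[k];
      double z = r[k] + W11(k, k) * old;  // partial residual
      double bnew;
      if (z > rho) bnew = (z - rho) / W11(k, k);
      else if (z < -rho) bnew = (z + rho) / W11(k, k);
      else bnew = 0.0;
      double d = bnew - old;
      if (d != 0.0) {
        beta[k] = bnew;
        for (int l = 0; l < p; ++l) r[l] -= W11(l, k) * d;
        double ad = std::abs(d);
        if (ad > maxdiff) maxdiff = ad;
      }
    }
    if (maxdiff < tol) break;
  }
  return beta;
}

static inline double dmin(double a, double b) { return a < b ? a : b; }
static inline double dmax(double a, double b) { return a > b ? a : b; }

// Grayscale morphological reconstruction by dilation of `marker` under
// `mask` (8-connectivity), hybrid raster/anti-raster algorithm with a
// FIFO cleanup pass. Inputs are matrices with marker <= mask elementwise.
// [[Rcpp::export(name = ".grey_reconstruct")]]
NumericMatrix grey_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  // clamp marker under mask
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (J(i, j) > mask(i, j)) J(i, j) = mask(i, j);

  // raster scan: neighbours already visited are (i-1,j-1),(i,j-1),(i+1,j-1),(i-1,j)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = J(i, j);
      if (j > 0) {
        v = dmax(v, J(i, j - 1));
        if (i > 0) v = dmax(v, J(i - 1, j - 1));
        if (i < nr - 1) v = dmax(v, J(i + 1, j - 1));
      }
      if (i > 0) v = dmax(v, J(i - 1, j));
      J(i, j) = dmin(v, mask(i, j));
    }
  }
  // anti-raster scan + queue seeding
  std::queue<std::pair<int, int> > fifo;
  for (int j = nc - 1; j >= 0; --j) {
    for (int i = nr - 1; i >= 0; --i) {
      double v = J(i, j);
      if (j < nc - 1) {
        v = dmax(v, J(i, j + 1));
        if (i > 0) v = dmax(v, J(i - 1, j + 1));
        if (i < nr - 1) v = dmax(v, J(i + 1, j + 1));
      }
      if (i < nr - 1) v = dmax(v, J(i + 1, j));
      J(i, j) = dmin(v, mask(i, j));
      // queue pixel if some anti-raster neighbour could still be raised
      double cur = J(i, j);
      bool push = false;
      if (j < nc - 1) {
        if (J(i, j + 1) < cur && J(i, j + 1) < mask(i, j + 1)) push = true;
        if (i > 0 && J(i - 1, j + 1) < cur && J(i - 1, j + 1) < mask(i - 1, j + 1)) push = true;
        if (i < nr - 1 && J(i + 1, j + 1) < cur && J(i + 1, j + 1) < mask(i + 1, j + 1)) push = true;
      }
      if (i < nr - 1 && J(i + 1, j) < cur && J(i + 1, j) < mask(i + 1, j)) push = true;
      if (push) fifo.push(std::make_pair(i, j));
    }
  }
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    std::pair<int, int> p = fifo.front();
    fifo.pop();
    int i = p.first, j = p.second;
    double cur = J(i, j);
    for (int k = 0; k < 8; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < cur && J(ii, jj) < mask(ii, jj)) {
        J(ii, jj) = dmin(cur, mask(ii, jj));
        fifo.push(std::make_pair(ii, jj));
      }
    }
  }
  return J;
}

// Count of y_j strictly less than and strictly greater than each x_i,
// given sorted y. Used by the O((n+m) log m) Cliff's delta.
// [[Rcpp::export(name = ".dominance_counts")]]
IntegerMatrix dominance_counts(NumericVector x, NumericVector ysort) {
  int n = x.size(), m = ysort.size();
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    // lower_bound: first index with y >= x_i  -> count of y < x_i
    int lo = std::lower_bound(ysort.begin(), ysort.end(), x[i]) - ysort.begin();
    // upper_bound: first index with y > x_i   -> m - that = count of y > x_i
    int hi = std::upper_bound(ysort.begin(), ysort.end(), x[i]) - ysort.begin();
    out(i, 0) = lo;
    out(i, 1) = m - hi;
  }
  return out;
}
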