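// Chain engines for sampling the flux polytope {v : Sv = 0, lb <= v <= ub}.
//
// All randomness comes from R's RNG (unif_rand / norm_rand), so set.seed()
// at the R level makes every chain exactly reproducible. The mass-balance
// equality is maintained by construction (directions lie in null(S)) and
// floating-point drift is removed by periodic orthogonal projection with
// the cached projector P = N N' onto null(S).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void projectClamp(arma::vec &x, const arma::mat &proj,
                                const arma::vec &lb, const arma::vec &ub,
                                double boundTol) {
  x = proj * x;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    if (x[i] < lb[i] && lb[i] - x[i] <= boundTol) x[i] = lb[i];
    else if (x[i] > ub[i] && x[i] - ub[i] <= boundTol) x[i] = ub[i];
  }
}

// tightest [amin, amax] containing 0 with lb <= x + a*d <= ub on components
// where |d_i| > dirTol; cap when a side is unconstrained
static inline void segmentLimits(const arma::vec &x, const arma::vec &d,
                                 const arma::vec &lb, const arma::vec &ub,
                                 double dirTol, double cap,
                                 double &amin, double &amax) {
  amin = -cap;
  amax = cap;
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    double di = d[i];
    if (std::abs(di) <= dirTol) continue;
    double lo = (lb[i] - x[i]) / di;
    double hi = (ub[i] - x[i]) / di;
    if (di > 0) {
      if (lo > amin) amin = lo;
      if (hi < amax) amax = hi;
    } else {
      if (hi > amin) amin = hi;
      if (lo < amax) amax = lo;
    }
  }
  if (amin > 0) amin = 0;
  if (amax < 0) amax = 0;
}

// [[Rcpp::export(.lineLimitsCpp)]]
NumericVector lineLimitsCpp(NumericVector point, NumericVector direction,
                            NumericVector lb, NumericVector ub,
                            double dirTol, double cap) {
  arma::vec x(point.begin(), point.size());
  arma::vec d(direction.begin(), direction.size());
  arma::vec l(lb.begin(), lb.size()), u(ub.begin(), ub.size());
  double amin, amax;
  segmentLimits(x, d, l, u, dirTol, cap, amin, amax);
  return NumericVector::create(amin, amax);
}

// One ACHR chain: nStore * thin iterates from x0, storing every thin-th
// point. Directions run from a uniformly drawn pool point toward the running
// empirical center, which absorbs every iterate. When poolGrows, stored
// samples join the direction pool (the long-chain scheme); otherwise the
// pool stays the warm-up set (the restart scheme).
// [[Rcpp::export(.achrChainCpp)]]
List achrChainCpp(NumericMatrix warmup, NumericVector x0, NumericVector center0,
                  double k0, int nStore, int thin,
                  NumericVector lb, NumericVector ub,
                  NumericMatrix proj, int projectEvery, bool poolGrows,
                  double dirTol, double boundTol) {
  const int n = x0.size();
  const int W = warmup.nrow();
  arma::mat pool(W + (poolGrows ? nStore : 0), n);
  for (int i = 0; i < W; ++i)
    for (int j = 0; j < n; ++j) pool(i, j) = warmup(i, j);
  int poolSize = W;

  arma::vec x(x0.begin(), n), center(center0.begin(), n);
  arma::vec l(lb.begin(), n), u(ub.begin(), n);
  arma::mat P(proj.begin(), n, n);
  arma::mat out(nStore, n);
  double k = k0;
  long iter = 0;

  for (int s = 0; s < nStore; ++s) {
    for (int t = 0; t < thin; ++t) {
      arma::vec d(n);
      double amin = 0, amax = 0;
      bool ok = false;
      double cap = 1e6 * (1.0 + arma::norm(x));
      for (int attempt = 0; attempt < 10; ++attempt) {
        int idx = (int)std::floor(unif_rand() * poolSize);
        if (idx >= poolSize) idx = poolSize - 1;
        d = pool.row(idx).t() - center;
        double nd = arma::norm(d);
        if (nd < dirTol) continue;
        d /= nd;
        segmentLimits(x, d, l, u, dirTol, cap, amin, amax);
        if (amax - amin < 1e-12) continue;
        ok = true;
        break;
      }
      if (!ok)
        stop("degenerate direction pool: no usable direction in 10 draws");
      double alpha = amin + unif_rand() * (amax - amin);
      x += alpha * d;
      k += 1.0;
      center += (x - center) / k;
      ++iter;
      if (projectEvery > 0 && iter % projectEvery == 0)
        projectClamp(x, P, l, u, boundTol);
    }
    projectClamp(x, P, l, u, boundTol);
    out.row(s) = x.t();
    if (poolGrows) {
      pool.row(poolSize) = x.t();
      ++poolSize;
    }
  }
  return List::create(_["samples"] = wrap(out), _["x"] = wrap(x),
                      _["center"] = wrap(center), _["k"] = k);
}

// Plain hit-and-run: isotropic directions in null(S) (fixed coordinates
// pinned to zero), uniform step on the feasible segment.
// [[Rcpp::export(.hrChainCpp)]]
List hrChainCpp(NumericVector x0, NumericMatrix dirBasis,
                int nStore, int thin,
                NumericVector lb, NumericVector ub,
                NumericMatrix proj, int projectEvery, double dirTol,
                double boundTol) {
  const int n = x0.size();
  const int kdim = dirBasis.ncol();
  arma::vec x(x0.begin(), n);
  arma::vec l(lb.begin(), n), u(ub.begin(), n);
  arma::mat B(dirBasis.begin(), n, kdim);
  arma::mat P(proj.begin(), n, n);
  arma::mat out(nStore, n);
  long iter = 0;

  for (int s = 0; s < nStore; ++s) {
    for (int t = 0; t < thin; ++t) {
      arma::vec d(n);
      double amin = 0, amax = 0;
      bool ok = false;
      double cap = 1e6 * (1.0 + arma::norm(x));
      for (int attempt = 0; attempt < 10; ++attempt) {
        arma::vec z(kdim);
        for (int j = 0; j < kdim; ++j) z[j] = norm_rand();
        d = B * z;
        double nd = arma::norm(d);
        if (nd < dirTol) continue;
        d /= nd;
        segmentLimits(x, d, l, u, dirTol, cap, amin, amax);
        if (amax - amin < 1e-12) continue;
        ok = true;
        break;
      }
      if (!ok)
        stop("degenerate state: no usable hit-and-run direction in 10 draws");
      double alpha = amin + unif_rand() * (amax - amin);
      x += alpha * d;
      ++iter;
      if (projectEvery > 0 && iter % projectEvery == 0)
        projectClamp(x, P, l, u, boundTol);
    }
    projectClamp(x, P, l, u, boundTol);
    out.row(s) = x.t();
  }
  return List::create(_["samples"] = wrap(out), _["x"] = wrap(x));
}
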