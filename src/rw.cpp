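#include <Rcpp.h>
using namespace Rcpp;

// Rescorla-Wagner avoidance-probability recursion:
//   p(1) = v1;  p(t+1) = p(t) + alpha * (beta - p(t))
// No outcome term: the trajectory is deterministic given (alpha, beta, v1).

// [[Rcpp::export(name = ".rw_traj_cpp")]]
NumericVector rw_traj_cpp(double alpha, double beta, double v1, int n) {
  NumericVector p(n);
  double cur = v1;
  for (int t = 0; t < n; ++t) {
    p[t] = cur;
    cur += alpha * (beta - cur);
  }
  return p;
}

// [[Rcpp::export(name = ".rw_sse_cpp")]]
double rw_sse_cpp(double alpha, double beta, double v1, NumericVector y) {
  int n = y.size();
  double cur = v1, sse = 0.0;
  for (int t = 0; t < n; ++t) {
    double d = y[t] - cur;
    sse += d * d;
    cur += alpha * (beta - cur);
  }
  return sse;
}

// Evaluate the SSE on a full grid of starts and return the k best
// (alpha, beta, v1, sse) rows, ordered by sse then alpha.
// [[Rcpp::export(name = ".rw_grid_cpp")]]
NumericMatrix rw_grid_cpp(NumericVector y, NumericVector grid, int k) {
  int g = grid.size();
  int total = g * g * g;
  std::vector<std::pair<double, int> > scored(total);
  int idx = 0;
  for (int ia = 0; ia < g; ++ia)
    for (int ib = 0; ib < g; ++ib)
      for (int iv = 0; iv < g; ++iv) {
        double sse = rw_sse_cpp(grid[ia], grid[ib], grid[iv], y);
        scored[idx] = std::make_pair(sse, idx);
        ++idx;
      }
  if (k > total) k = total;
  std::partial_sort(scored.begin(), scored.begin() + k, scored.end());
  NumericMatrix out(k, 4);
  for (int i = 0; i < k; ++i) {
    int j = scored[i].second;
    int ia = j / (g * g), ib = (j / g) % g, iv = j % g;
    out(i, 0) = grid[ia];
    out(i, 1) = grid[ib];
    out(i, 2) = grid[iv];
    out(i, 3) = scored[i].first;
  }
  return out;
}

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

static inline double inv_logit(double z) { return 1.0 / (1.0 + std::exp(-z)); }
static inline double logit_c(double p) {
  if (p < 1e-8) p = 1e-8;
  if (p > 1.0 - 1e-8) p = 1.0 - 1e-8;
  return std::log(p / (1.0 - p));
}

static double sse_z(const double* z, NumericVector& y) {
  return rw_sse_cpp(inv_logit(z[0]), inv_logit(z[1]), inv_logit(z[2]), y);
}

// Nelder-Mead on the logit scale (keeps parameters inside (0,1)).
static void nelder_mead(double* z, double& fbest, NumericVector& y,
                        double step, int maxit, double ftol) {
  const int n = 3;
  double simplex[4][3], fv[4];
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j < n; ++j) simplex[i][j] = z[j];
    if (i > 0) simplex[i][i - 1] += step;
    fv[i] = sse_z(simplex[i], y);
  }
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i <= n; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    nh = (hi == 0) ? 1 : 0;
    for (int i = 0; i <= n; ++i)
      if (i != hi && fv[i] > fv[nh]) nh = i;
    if (std::fabs(fv[hi] - fv[lo]) <= ftol * (std::fabs(fv[lo]) + 1e-300) ||
        fv[hi] - fv[lo] < 1e-300) break;
    double cen[3] = {0, 0, 0};
    for (int i = 0; i <= n; ++i)
      if (i != hi)
        for (int j = 0; j < n; ++j) cen[j] += simplex[i][j] / n;
    double refl[3], fr;
    for (int j = 0; j < n; ++j) refl[j] = cen[j] + (cen[j] - simplex[hi][j]);
    fr = sse_z(refl, y);
    if (fr < fv[lo]) {
      double exp_[3], fe;
      for (int j = 0; j < n; ++j) exp_[j] = cen[j] + 2.0 * (cen[j] - simplex[hi][j]);
      fe = sse_z(exp_, y);
      if (fe < fr) {
        std::copy(exp_, exp_ + 3, simplex[hi]); fv[hi] = fe;
      } else {
        std::copy(refl, refl + 3, simplex[hi]); fv[hi] = fr;
      }
    } else if (fr < fv[nh]) {
      std::copy(refl, refl + 3, simplex[hi]); fv[hi] = fr;
    } else {
      double con[3], fc;
      for (int j = 0; j < n; ++j) con[j] = cen[j] + 0.5 * (simplex[hi][j] - cen[j]);
      fc = sse_z(con, y);
      if (fc < fv[hi]) {
        std::copy(con, con + 3, simplex[hi]); fv[hi] = fc;
      } else {
        for (int i = 0; i <= n; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < n; ++j)
            simplex[i][j] = simplex[lo][j] + 0.5 * (simplex[i][j] - simplex[lo][j]);
          fv[i] = sse_z(simplex[i], y);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i <= n; ++i) if (fv[i] < fv[lo]) lo = i;
  std::copy(simplex[lo], simplex[lo] + 3, z);
  fbest = fv[lo];
}

// Full multi-start least-squares fit: grid of starts, Nelder-Mead
// refinement of the best `n_refine`, with a small-step polish restart.
// Returns (alpha, beta, v1, sse); ties broken by sse then alpha.
// [[Rcpp::export(name = ".rw_fit_cpp")]]
NumericVector rw_fit_cpp(NumericVector y, NumericVector grid, int n_refine) {
  NumericMatrix starts = rw_grid_cpp(y, grid, n_refine);
  double best[3] = {0, 0, 0};
  double fbest = R_PosInf, abest = R_PosInf;
  for (int i = 0; i < starts.nrow(); ++i) {
    double z[3] = {logit_c(starts(i, 0)), logit_c(starts(i, 1)),
                   logit_c(starts(i, 2))};
    double f = starts(i, 3);
    nelder_mead(z, f, y, 1.0, 500, 1e-14);
    nelder_mead(z, f, y, 0.05, 500, 1e-16);
    nelder_mead(z, f, y, 0.002, 300, 1e-16);
    double a = inv_logit(z[0]);
    if (f < fbest - 1e-15 ||
        (std::fabs(f - fbest) <= 1e-15 && a < abest)) {
      fbest = f;
      abest = a;
      for (int j = 0; j < 3; ++j) best[j] = inv_logit(z[j]);
    }
  }
  return NumericVector::create(clamp01(best[0]), clamp01(best[1]),
                               clamp01(best[2]), fbest);
}

// Bernoulli log-likelihood of a 0/1 outcome sequence under the recursion,
// probabilities clipped to [eps, 1 - eps].
// [[Rcpp::export(name = ".rw_loglik_cpp")]]
double rw_loglik_cpp(double alpha, double beta, double v1,
                     IntegerVector y, double eps) {
  int n = y.size();
  double cur = v1, ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double p = cur;
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += y[t] ? std::log(p) : std::log1p(-p);
    cur += alpha * (beta - cur);
  }
  return ll;
}
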