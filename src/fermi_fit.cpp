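// Per-pixel Fermi-constrained deconvolution fits.
//
// The tissue model is amp * (C %*% r(k, w, d)) where C is the trapezoidal
// convolution matrix built from the arterial input function and r is the
// unit-amplitude Fermi impulse response sampled at the frame lags. The
// amplitude is profiled out analytically (linear least squares, clamped to
// its bounds), leaving a 3-parameter problem solved by a bounded
// Nelder-Mead search started from the best cells of a coarse parameter
// grid. Everything is deterministic: no RNG anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void fermi_unit(const vec& lags, double k, double w, double d, vec& r) {
  const uword n = lags.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double t = lags[i];
    if (t >= d) {
      const double e = k * (t - d - w);
      // guard exp overflow for large positive arguments
      r[i] = (e > 700.0) ? 0.0 : 1.0 / (1.0 + std::exp(e));
    } else {
      r[i] = 0.0;
    }
  }
}

struct PixelObjective {
  const vec* y;
  const mat* C;
  const vec* lags;
  vec lo, hi;          // (k, w, d) bounds
  double amp_lo, amp_hi;
  double yy;
  mutable vec r, m;
  mutable double last_amp;

  // bounds handled by clamping: the objective is evaluated at the
  // projection of the proposed point onto the box
  vec to_theta(const vec& u) const {
    vec th(3);
    for (int j = 0; j < 3; ++j) {
      double v = u[j];
      if (v < lo[j]) v = lo[j];
      if (v > hi[j]) v = hi[j];
      th[j] = v;
    }
    return th;
  }

  double rss_at(double k, double w, double d, double* amp_out) const {
    fermi_unit(*lags, k, w, d, r);
    m = (*C) * r;
    const double mm = dot(m, m);
    double amp = 0.0;
    if (mm > 1e-300) amp = dot(*y, m) / mm;
    if (amp < amp_lo) amp = amp_lo;
    if (amp > amp_hi) amp = amp_hi;
    double rss = yy - 2.0 * amp * dot(*y, m) + amp * amp * mm;
    if (rss < 0.0) rss = 0.0;
    if (amp_out) *amp_out = amp;
    return rss;
  }

  double operator()(const vec& u) const {
    vec th = to_theta(u);
    return rss_at(th[0], th[1], th[2], &last_amp);
  }
};

// Standard Nelder-Mead on 3 parameters (box handled by clamping in f).
// `scale` sets an absolute convergence floor so exact (zero-residual) fits
// can terminate: the simplex spread is compared against
// tol * |f_best| + 1e-12 * scale.
static void nelder_mead(const PixelObjective& f, vec& u, double& fval,
                        int maxit, double tol, double scale, bool& converged,
                        int& used) {
  const int n = 3;
  std::vector<vec> simplex(n + 1);
  std::vector<double> fv(n + 1);
  simplex[0] = u;
  fv[0] = f(u);
  for (int j = 0; j < n; ++j) {
    vec p = u;
    double step = 0.08 * (f.hi[j] - f.lo[j]);
    p[j] += (p[j] + step <= f.hi[j]) ? step : -step;
    simplex[j + 1] = p;
    fv[j + 1] = f(p);
  }
  used = n + 1;
  converged = false;
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> ord(n + 1);
    for (int j = 0; j <= n; ++j) ord[j] = j;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<vec> s2(n + 1);
    std::vector<double> f2(n + 1);
    for (int j = 0; j <= n; ++j) { s2[j] = simplex[ord[j]]; f2[j] = fv[ord[j]]; }
    simplex = s2; fv = f2;
    if (fv[n] - fv[0] <= tol * std::abs(fv[0]) + 1e-12 * scale) {
      converged = true;
      break;
    }
    vec cen = zeros<vec>(n);
    for (int j = 0; j < n; ++j) cen += simplex[j];
    cen /= n;
    vec xr = cen + alpha * (cen - simplex[n]);
    double fr = f(xr); ++used;
    if (fr < fv[0]) {
      vec xe = cen + gamma * (xr - cen);
      double fe = f(xe); ++used;
      if (fe < fr) { simplex[n] = xe; fv[n] = fe; }
      else { simplex[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      simplex[n] = xr; fv[n] = fr;
    } else {
      vec xc = cen + rho * (simplex[n] - cen);
      double fc = f(xc); ++used;
      if (fc < fv[n]) { simplex[n] = xc; fv[n] = fc; }
      else {
        for (int j = 1; j <= n; ++j) {
          simplex[j] = simplex[0] + sigma * (simplex[j] - simplex[0]);
          fv[j] = f(simplex[j]); ++used;
        }
      }
    }
  }
  int best = 0;
  for (int j = 1; j <= n; ++j) if (fv[j] < fv[best]) best = j;
  u = simplex[best];
  fval = fv[best];
}

// [[Rcpp::export]]
Rcpp::List fermi_fit_mat(const arma::mat& Y, const arma::mat& Cmat,
                         const arma::vec& lags, const arma::vec& k_grid,
                         const arma::vec& w_grid, const arma::vec& d_grid,
                         const arma::vec& lower, const arma::vec& upper,
                         double amp_lo, double amp_hi, int multistart,
                         int maxit, double tol) {
  const uword npix = Y.n_rows, n = Y.n_cols;
  const uword G = k_grid.n_elem * w_grid.n_elem * d_grid.n_elem;

  // grid of unit-amplitude model curves
  mat R(n, G);
  vec kg(G), wg(G), dg(G);
  {
    vec r(n);
    uword g = 0;
    for (uword a = 0; a < k_grid.n_elem; ++a)
      for (uword b = 0; b < w_grid.n_elem; ++b)
        for (uword c = 0; c < d_grid.n_elem; ++c) {
          fermi_unit(lags, k_grid[a], w_grid[b], d_grid[c], r);
          R.col(g) = r;
          kg[g] = k_grid[a]; wg[g] = w_grid[b]; dg[g] = d_grid[c];
          ++g;
        }
  }
  mat M = Cmat * R;                    // n x G
  rowvec mm = sum(M % M, 0);           // 1 x G
  mat YM = Y * M;                      // npix x G
  vec yy = sum(Y % Y, 1);

  vec out_amp(npix), out_k(npix), out_w(npix), out_d(npix), out_rss(npix);
  ivec out_conv(npix), out_neval(npix);

  const int nstart = std::max(1, std::min<int>(multistart, (int)G));

  for (uword p = 0; p < npix; ++p) {
    // grid RSS with clamped profiled amplitude
    vec rss_g(G);
    for (uword g = 0; g < G; ++g) {
      double amp = 0.0;
      if (mm[g] > 1e-300) amp = YM(p, g) / mm[g];
      if (amp < amp_lo) amp = amp_lo;
      if (amp > amp_hi) amp = amp_hi;
      double rg = yy[p] - 2.0 * amp * YM(p, g) + amp * amp * mm[g];
      rss_g[g] = (rg < 0.0) ? 0.0 : rg;
    }
    uvec ord = sort_index(rss_g);

    PixelObjective obj;
    vec yrow = Y.row(p).t();
    obj.y = &yrow; obj.C = &Cmat; obj.lags = &lags;
    obj.lo = lower; obj.hi = upper;
    obj.amp_lo = amp_lo; obj.amp_hi = amp_hi;
    obj.yy = yy[p];
    obj.r.set_size(n); obj.m.set_size(n);

    double best_rss = datum::inf, best_amp = 0.0, best_d = 0.0;
    vec best_th(3, fill::zeros);
    bool best_conv = false;
    int total_eval = 0;

    for (int s = 0; s < nstart; ++s) {
      uword g = ord[s];
      vec u(3);
      u[0] = kg[g]; u[1] = wg[g]; u[2] = dg[g];
      double fval;
      bool conv; int used;
      const double scale = std::max(yy[p], 1e-30);
      nelder_mead(obj, u, fval, maxit, tol, scale, conv, used);
      total_eval += used;
      // restart once from the solution to escape a collapsed simplex
      nelder_mead(obj, u, fval, maxit, tol, scale, conv, used);
      total_eval += used;
      vec th = obj.to_theta(u);
      double amp;
      double rss = obj.rss_at(th[0], th[1], th[2], &amp);
      const bool better = rss < best_rss * (1.0 - 1e-12) ||
        (std::abs(rss - best_rss) <= 1e-12 * (best_rss + 1e-300) &&
         th[2] < best_d);
      if (better) {
        best_rss = rss; best_amp = amp; best_th = th; best_d = th[2];
        best_conv = conv;
      }
    }
    out_amp[p] = best_amp;
    out_k[p] = best_th[0];
    out_w[p] = best_th[1];
    out_d[p] = best_th[2];
    out_rss[p] = best_rss;
    out_conv[p] = best_conv ? 1 : 0;
    out_neval[p] = total_eval;
  }

  return Rcpp::List::create(
    Rcpp::Named("amp") = out_amp, Rcpp::Named("k") = out_k,
    Rcpp::Named("w") = out_w, Rcpp::Named("delay") = out_d,
    Rcpp::Named("rss") = out_rss, Rcpp::Named("converged") = out_conv,
    Rcpp::Named("n_eval") = out_neval);
}
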