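#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Model codes shared with the R wrappers:
//   0 monoexponential            S(TE) = PD exp(-TE/T2)
//   1 offset                     S(TE) = PD exp(-TE/T2) + C
//   2 second moment, free k      M(TE) ~ sqrt((PD exp(-TE/T2))^2 + k)
//   3 second moment, fixed k     as 2 with k supplied (true-sigma comparator)
//
// Parameter vectors: (pd, t2[, c|k]).  Models 2 and 3 predict the measured
// magnitude by the square root of the noncentral-chi second moment, so
// residuals stay in the magnitude domain for every model.  Box constraints
// (pd >= 0, 0 < t2 <= t2_max, c/k >= 0) are enforced by a violation-scaled
// penalty so the simplex can slide back into the feasible region.

static const double T2_MIN = 1e-6;
static const double PENALTY = 1e12;

static double model_sse(const std::vector<double>& x,
                        const std::vector<double>& te,
                        const std::vector<double>& y,
                        int model, double t2_max, double k_fixed) {
  const double pd = x[0], t2 = x[1];
  double c = 0.0, k = k_fixed;
  double viol = 0.0;
  if (pd < 0.0) viol += -pd;
  if (t2 < T2_MIN) viol += (T2_MIN - t2);
  if (t2 > t2_max) viol += (t2 - t2_max);
  if (model == 1) { c = x[2]; if (c < 0.0) viol += -c; }
  if (model == 2) { k = x[2]; if (k < 0.0) viol += -k; }
  if (viol > 0.0) return PENALTY * (1.0 + viol);
  double sse = 0.0;
  const size_t n = te.size();
  for (size_t i = 0; i < n; ++i) {
    const double s = pd * std::exp(-te[i] / t2);
    double r;
    if (model <= 1) {
      r = y[i] - (s + c);
    } else {
      r = y[i] - std::sqrt(s * s + k);
    }
    sse += r * r;
  }
  return sse;
}

struct NmFit {
  std::vector<double> x;
  double f;
  int iter;
  bool converged;
};

// Nelder-Mead simplex with standard coefficients (reflect 1, expand 2,
// contract 0.5, shrink 0.5); initial simplex perturbs each coordinate by 5%
// (0.00025 absolute when zero).  Stops when both the function spread and the
// vertex spread fall below a relative tolerance of 1e-8.
template <typename F>
static NmFit nelder_mead(F fn, const std::vector<double>& x0,
                         double reltol = 1e-8, int maxit = 2000) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sig = 0.5;
  const int n = static_cast<int>(x0.size());
  std::vector<std::vector<double>> sx(n + 1, x0);
  for (int i = 0; i < n; ++i) {
    if (x0[i] != 0.0) sx[i + 1][i] = x0[i] * 1.05;
    else sx[i + 1][i] = 0.00025;
  }
  std::vector<double> fv(n + 1);
  for (int i = 0; i <= n; ++i) fv[i] = fn(sx[i]);

  std::vector<int> ord(n + 1);
  int iter = 0;
  bool conv = false;
  std::vector<double> cen(n), xr(n), xe(n), xc(n);

  while (iter < maxit) {
    std::iota(ord.begin(), ord.end(), 0);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<std::vector<double>> sx2(n + 1);
    std::vector<double> fv2(n + 1);
    for (int i = 0; i <= n; ++i) { sx2[i] = sx[ord[i]]; fv2[i] = fv[ord[i]]; }
    sx.swap(sx2);
    fv.swap(fv2);

    double fspread = std::fabs(fv[n] - fv[0]);
    double xspread = 0.0, xscale = 1.0;
    for (int j = 0; j < n; ++j) {
      xscale = std::max(xscale, std::fabs(sx[0][j]));
      for (int i = 1; i <= n; ++i)
        xspread = std::max(xspread, std::fabs(sx[i][j] - sx[0][j]));
    }
    if (fspread <= reltol * std::max(1.0, std::fabs(fv[0])) &&
        xspread <= reltol * xscale) {
      conv = true;
      break;
    }
    ++iter;

    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += sx[i][j];
      cen[j] = s / n;
    }
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + alpha * (cen[j] - sx[n][j]);
    const double fr = fn(xr);

    if (fr < fv[0]) {
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + gamma * (xr[j] - cen[j]);
      const double fe = fn(xe);
      if (fe < fr) { sx[n] = xe; fv[n] = fe; }
      else { sx[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      sx[n] = xr; fv[n] = fr;
    } else {
      bool shrink = false;
      if (fr < fv[n]) {  // outside contraction
        for (int j = 0; j < n; ++j) xc[j] = cen[j] + rho * (xr[j] - cen[j]);
        const double fc = fn(xc);
        if (fc <= fr) { sx[n] = xc; fv[n] = fc; }
        else shrink = true;
      } else {           // inside contraction
        for (int j = 0; j < n; ++j) xc[j] = cen[j] - rho * (cen[j] - sx[n][j]);
        const double fc = fn(xc);
        if (fc < fv[n]) { sx[n] = xc; fv[n] = fc; }
        else shrink = true;
      }
      if (shrink) {
        for (int i = 1; i <= n; ++i) {
          for (int j = 0; j < n; ++j)
            sx[i][j] = sx[0][j] + sig * (sx[i][j] - sx[0][j]);
          fv[i] = fn(sx[i]);
        }
      }
    }
  }

  int best = 0;
  for (int i = 1; i <= n; ++i) if (fv[i] < fv[best]) best = i;
  NmFit out;
  out.x = sx[best];
  out.f = fv[best];
  out.iter = iter;
  out.converged = conv;
  return out;
}

// Weighted least squares on the signal logarithm: regress log(y) on te with
// weights y^2; pd = exp(intercept), t2 = -1/slope.  Non-decaying fits (slope
// >= 0) and runaway slopes are clamped to t2_max.
static void wlsl_core(const std::vector<double>& te,
                      const std::vector<double>& y,
                      double t2_max, double& pd, double& t2) {
  long double sw = 0, swx = 0, swy = 0, swxx = 0, swxy = 0;
  const size_t n = te.size();
  for (size_t i = 0; i < n; ++i) {
    const long double w = (long double)y[i] * y[i];
    const long double x = te[i];
    const long double ly = std::log(y[i]);
    sw += w; swx += w * x; swy += w * ly;
    swxx += w * x * x; swxy += w * x * ly;
  }
  const long double den = sw * swxx - swx * swx;
  double slope, icpt;
  if (den <= 0) {
    slope = 0.0;
    icpt = (double)(swy / sw);
  } else {
    slope = (double)((sw * swxy - swx * swy) / den);
    icpt = (double)((swxx * swy - swx * swxy) / den);
  }
  pd = std::exp(icpt);
  if (slope < 0.0) t2 = std::min(-1.0 / slope, t2_max);
  else t2 = t2_max;
  if (t2 < T2_MIN) t2 = T2_MIN;
}

// [[Rcpp::export]]
NumericVector cpp_wlsl(NumericVector te, NumericVector y, double t2_max) {
  std::vector<double> tev(te.begin(), te.end());
  std::vector<double> yv(y.begin(), y.end());
  double pd, t2;
  wlsl_core(tev, yv, t2_max, pd, t2);
  return NumericVector::create(pd, t2);
}

static NmFit fit_one(int model, const std::vector<double>& te,
                     const std::vector<double>& y,
                     const std::vector<double>& init,
                     double t2_max, double k_fixed) {
  auto fn = [&](const std::vector<double>& x) {
    return model_sse(x, te, y, model, t2_max, k_fixed);
  };
  return nelder_mead(fn, init);
}

// [[Rcpp::export]]
List cpp_fit_model(int model, NumericVector te, NumericVector y,
                   NumericVector init, double t2_max,
                   double k_fixed = 0.0) {
  std::vector<double> tev(te.begin(), te.end());
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> x0(init.begin(), init.end());
  NmFit r = fit_one(model, tev, yv, x0, t2_max, k_fixed);
  return List::create(_["params"] = NumericVector(r.x.begin(), r.x.end()),
                      _["sse"] = r.f,
                      _["n_iterations"] = r.iter,
                      _["converged"] = r.converged);
}

// Positive copy of a magnitude series for the log-domain initializer;
// non-positive entries (possible only for degenerate input) are replaced
// by a small fraction of the smallest positive value.
static std::vector<double> positive_clamp(const std::vector<double>& y) {
  double minpos = R_PosInf;
  for (double v : y) if (v > 0 && v < minpos) minpos = v;
  if (!R_FINITE(minpos)) minpos = 1.0;
  std::vector<double> out(y);
  for (double& v : out) if (v <= 0) v = minpos * 1e-3;
  return out;
}

struct AdaptsOut {
  double t2, t2_initial, pd, extra, sse;
  int branch, n_kept, iter;
  bool converged, prefit_converged;
};

// Full model-switching estimate on one ROI-averaged magnitude series.
// branch: 0 = truncation (two-parameter monoexponential on retained echoes),
//         1 = noise-corrected (three-parameter second-moment on all echoes).
static AdaptsOut adapts_core(const std::vector<double>& te,
                             const std::vector<double>& y,
                             double p1, double p2) {
  const size_t n = te.size();
  const double t2_max = 10.0 * te[n - 1];
  std::vector<double> ypos = positive_clamp(y);

  double pd0, t20;
  wlsl_core(te, ypos, t2_max, pd0, t20);

  // Offset-model pre-fit on all echoes; C starts at the observed minimum,
  // the closest observable proxy for the noise plateau.  The decay part is
  // initialized by WLSL on the offset-subtracted series: on floor-dominated
  // signals (very short T2*) plain WLSL sees a nearly flat series and
  // starts the simplex in a shallow large-T2* basin.
  const double ymin = *std::min_element(y.begin(), y.end());
  std::vector<double> ysub(y);
  for (double& v : ysub) v -= ymin;
  ysub = positive_clamp(ysub);
  double pd_off, t2_off;
  wlsl_core(te, ysub, t2_max, pd_off, t2_off);
  std::vector<double> init_off = {pd_off, t2_off, std::max(ymin, 0.0)};
  NmFit pre = fit_one(1, te, y, init_off, t2_max, 0.0);
  double t2_initial = pre.x[1];

  // A pre-fit that stops at the iteration cap still carries its best
  // vertex; truncation uses that estimate as-is.  At the clamp ceiling the
  // threshold exceeds every TE, so all echoes are naturally retained.
  std::vector<int> kept;
  const double thr = p1 * t2_initial;
  for (size_t i = 0; i < n; ++i) {
    if (te[i] <= thr) kept.push_back(static_cast<int>(i));
  }

  AdaptsOut out;
  out.t2_initial = t2_initial;
  out.prefit_converged = pre.converged;
  out.n_kept = static_cast<int>(kept.size());

  if (out.n_kept >= p2 && out.n_kept >= 2) {
    // Truncation branch: monoexponential fit on retained echoes.
    std::vector<double> tek, yk, ykpos;
    for (int i : kept) { tek.push_back(te[i]); yk.push_back(y[i]); }
    ykpos = positive_clamp(yk);
    double pdk, t2k;
    wlsl_core(tek, ykpos, t2_max, pdk, t2k);
    std::vector<double> init_m = {pdk, t2k};
    NmFit fin = fit_one(0, tek, yk, init_m, t2_max, 0.0);
    out.branch = 0;
    out.t2 = fin.x[1];
    out.pd = fin.x[0];
    out.extra = 0.0;
    out.sse = fin.f;
    out.iter = fin.iter;
    out.converged = fin.converged;
  } else {
    // Noise-corrected branch: second-moment fit with free noise term on all
    // echoes; k starts at the smallest squared magnitude.
    double y2min = y[0] * y[0];
    for (double v : y) y2min = std::min(y2min, v * v);
    std::vector<double> init_k = {pd0, t20, y2min};
    NmFit fin = fit_one(2, te, y, init_k, t2_max, 0.0);
    out.branch = 1;
    out.t2 = fin.x[1];
    out.pd = fin.x[0];
    out.extra = fin.x[2];
    out.sse = fin.f;
    out.iter = fin.iter;
    out.converged = fin.converged;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_adapts(NumericVector te, NumericVector y, double p1, double p2) {
  std::vector<double> tev(te.begin(), te.end());
  std::vector<double> yv(y.begin(), y.end());
  AdaptsOut r = adapts_core(tev, yv, p1, p2);
  return List::create(_["t2"] = r.t2,
                      _["branch"] = r.branch,
                      _["t2_initial"] = r.t2_initial,
                      _["n_kept"] = r.n_kept,
                      _["pd"] = r.pd,
                      _["extra"] = r.extra,
                      _["sse"] = r.sse,
                      _["n_iterations"] = r.iter,
                      _["converged"] = r.converged,
                      _["prefit_converged"] = r.prefit_converged);
}

// Column-wise model-switching estimates for a matrix of magnitude series
// (rows = echoes, columns = independent signals).  Returns a matrix with one
// row per signal: t2, branch, t2_initial, n_kept, converged.
// [[Rcpp::export]]
NumericMatrix cpp_adapts_batch(NumericVector te, NumericMatrix y,
                               double p1, double p2) {
  const int n = y.nrow(), m = y.ncol();
  std::vector<double> tev(te.begin(), te.end());
  NumericMatrix out(m, 5);
  std::vector<double> yv(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) yv[i] = y(i, j);
    AdaptsOut r = adapts_core(tev, yv, p1, p2);
    out(j, 0) = r.t2;
    out(j, 1) = r.branch;
    out(j, 2) = r.t2_initial;
    out(j, 3) = r.n_kept;
    out(j, 4) = r.converged ? 1.0 : 0.0;
  }
  colnames(out) = CharacterVector::create("t2", "branch", "t2_initial",
                                          "n_kept", "converged");
  return out;
}

// Column-wise two-parameter second-moment fits with the noise term held at a
// known value (the true-sigma comparator).  Returns t2 and convergence flag.
// [[Rcpp::export]]
NumericMatrix cpp_m2ncm_batch(NumericVector te, NumericMatrix y,
                              double k_fixed) {
  const int n = y.nrow(), m = y.ncol();
  std::vector<double> tev(te.begin(), te.end());
  const double t2_max = 10.0 * tev[n - 1];
  NumericMatrix out(m, 2);
  std::vector<double> yv(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) yv[i] = y(i, j);
    std::vector<double> ypos = positive_clamp(yv);
    double pd0, t20;
    wlsl_core(tev, ypos, t2_max, pd0, t20);
    std::vector<double> init = {pd0, t20};
    NmFit r = fit_one(3, tev, yv, init, t2_max, k_fixed);
    out(j, 0) = r.x[1];
    out(j, 1) = r.converged ? 1.0 : 0.0;
  }
  colnames(out) = CharacterVector::create("t2", "converged");
  return out;
}

// Multi-coil RSS magnitude simulator.  Each pixel: every coil carries the
// identical monoexponential decay s0 exp(-TE/t2) on both the real and the
// imaginary channel plus independent N(0, sigma^2) noise per component;
// coil magnitudes combine by root sum of squares, so the noiseless RSS
// magnitude at TE = 0 is sqrt(2 L) s0.  Draw order (pixel-major; per coil,
// per echo: real then imaginary) is fixed so seeded runs are
// bit-reproducible.  Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_pixels(NumericVector te, double t2, double s0,
                                  double sigma, int n_coils, int n_pixels) {
  const int n = te.size();
  const double a = s0;
  std::vector<double> decay(n);
  for (int i = 0; i < n; ++i) decay[i] = a * std::exp(-te[i] / t2);
  NumericMatrix out(n, n_pixels);
  std::vector<double> acc(n);
  for (int p = 0; p < n_pixels; ++p) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int l = 0; l < n_coils; ++l) {
      for (int i = 0; i < n; ++i) {
        const double re = decay[i] + sigma * norm_rand();
        const double im = decay[i] + sigma * norm_rand();
        acc[i] += re * re + im * im;
      }
    }
    for (int i = 0; i < n; ++i) out(i, p) = std::sqrt(acc[i]);
  }
  return out;
}

// Means of consecutive column groups of fixed size (ROI / subregion
// averaging).  ncol(y) must be a multiple of group_size.
// [[Rcpp::export]]
NumericMatrix cpp_group_means(NumericMatrix y, int group_size) {
  const int n = y.nrow(), m = y.ncol();
  const int g = m / group_size;
  NumericMatrix out(n, g);
  for (int b = 0; b < g; ++b) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < group_size; ++j) s += y(i, b * group_size + j);
      out(i, b) = s / group_size;
    }
  }
  return out;
}
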