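#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-compartment exchange model (2CXM).
//
// State (Cp, Ce) evolves as
//   vp dCp/dt = Fp (Ca(t) - Cp) + PS (Ce - Cp),   Fp = Fb / (1 - Hct)
//   ve dCe/dt = PS (Cp - Ce)
// and the measured tissue concentration is C = vp Cp + ve Ce.
// The impulse response is h(t) = Fp R(t) with the bi-exponential residue
// function R(t) = A exp(th1 t) + (1 - A) exp(th2 t), th1 <= th2 < 0 the
// eigenvalues of the compartment matrix.

struct CxmExp {
  double th1, th2;  // eigenvalues (non-positive)
  double A;         // weight of the th1 component, R = A e^{th1 t} + (1-A) e^{th2 t}
  bool degenerate;  // eigenvalues coincide within tolerance
};

static CxmExp cxm_exponents(double fb, double vp, double ve, double ps,
                            double hct) {
  const double fp = fb / (1.0 - hct);
  const double a = (fp + ps) / vp;  // plasma efflux rate
  const double b = ps / ve;         // interstitium exchange rate
  const double c = ps / vp;
  const double sum = a + b;
  // (a+b)^2 - 4(ab - cb) = (a-b)^2 + 4cb >= 0: eigenvalues always real
  const double disc = std::sqrt((a - b) * (a - b) + 4.0 * c * b);
  CxmExp e;
  e.th1 = -(sum + disc) / 2.0;
  e.th2 = -(sum - disc) / 2.0;
  e.degenerate = (disc <= 1e-9 * sum);
  if (e.degenerate) {
    e.A = 1.0;  // limiting form handled separately by callers
  } else {
    // A = (-Fp/vp - th2) / (th1 - th2); A + (1-A) = 1 so R(0) = 1
    e.A = (-fp / vp - e.th2) / (e.th1 - e.th2);
  }
  return e;
}

// [[Rcpp::export(name = ".cxm_exponents_cpp")]]
NumericVector cxm_exponents_cpp(double fb, double vp, double ve, double ps,
                                double hct) {
  CxmExp e = cxm_exponents(fb, vp, ve, ps, hct);
  return NumericVector::create(_["th1"] = e.th1, _["th2"] = e.th2,
                               _["A"] = e.A,
                               _["degenerate"] = e.degenerate ? 1.0 : 0.0);
}

// Residue function sampled on an arbitrary time grid (times >= 0).
// [[Rcpp::export(name = ".cxm_residue_cpp")]]
NumericVector cxm_residue_cpp(NumericVector times, double fb, double vp,
                              double ve, double ps, double hct) {
  CxmExp e = cxm_exponents(fb, vp, ve, ps, hct);
  const double fp = fb / (1.0 - hct);
  const int n = times.size();
  NumericVector out(n);
  if (e.degenerate) {
    // e^{Mt} = e^{th t} (I + (M - th I) t):  R = e^{th t} (1 + (-Fp/vp - th) t)
    const double th = (e.th1 + e.th2) / 2.0;
    const double slope = -fp / vp - th;
    for (int i = 0; i < n; ++i)
      out[i] = std::exp(th * times[i]) * (1.0 + slope * times[i]);
  } else {
    for (int i = 0; i < n; ++i)
      out[i] = e.A * std::exp(e.th1 * times[i]) +
               (1.0 - e.A) * std::exp(e.th2 * times[i]);
  }
  return out;
}

// exact integrals of e^{th s} and s e^{th s} over [0, dt] (series for small th*dt)
static inline void exp_integrals(double th, double dt, double &i0, double &i1) {
  const double x = th * dt;
  if (std::fabs(x) < 1e-6) {
    i0 = dt * (1.0 + x / 2.0 + x * x / 6.0);
    i1 = dt * dt * (0.5 + x / 3.0 + x * x / 8.0);
  } else {
    const double ex = std::exp(x);
    i0 = (ex - 1.0) / th;
    i1 = (dt * ex - i0) / th;
  }
}

// One exponential component E e^{th t} convolved with the piecewise-linear
// interpolant of `a` on a uniform grid with spacing dt; exact recursion
//   y_j = e^{th dt} y_{j-1} + E * int_0^{dt} e^{th s} a(t_j - s) ds.
static void conv_exp_linear(const std::vector<double> &a, double dt, double E,
                            double th, std::vector<double> &y) {
  const int n = (int)a.size();
  double i0, i1;
  exp_integrals(th, dt, i0, i1);
  const double decay = std::exp(th * dt);
  double prev = 0.0;
  y[0] += 0.0;
  for (int j = 1; j < n; ++j) {
    const double local = a[j] * i0 + (a[j - 1] - a[j]) / dt * i1;
    prev = decay * prev + E * local;
    y[j] += prev;
  }
}

// component E * t e^{th t} (degenerate eigenvalue limit), same scheme:
// carries the pair (y, z) with z the plain-exponential convolution, using
// t_j - s = (t_{j-1} - s) + dt.
static void conv_texp_linear(const std::vector<double> &a, double dt, double E,
                             double th, std::vector<double> &y) {
  const int n = (int)a.size();
  double i0, i1;
  exp_integrals(th, dt, i0, i1);
  const double decay = std::exp(th * dt);
  // i2 = int_0^dt s^2 e^{th s} ds
  double i2;
  const double x = th * dt;
  if (std::fabs(x) < 1e-6) {
    i2 = dt * dt * dt * (1.0 / 3.0 + x / 4.0 + x * x / 10.0);
  } else {
    i2 = (dt * dt * std::exp(x) - 2.0 * i1) / th;
  }
  double yprev = 0.0, zprev = 0.0;
  for (int j = 1; j < n; ++j) {
    const double slope = (a[j - 1] - a[j]) / dt;
    const double l0 = a[j] * i0 + slope * i1;       // int e^{th s} a(t_j - s)
    const double l1 = a[j] * i1 + slope * i2;       // int s e^{th s} a(t_j - s)
    const double ynew = decay * (yprev + dt * zprev) + E * l1;
    const double znew = decay * zprev + E * l0;
    yprev = ynew;
    zprev = znew;
    y[j] += ynew;
  }
}

// Shift the AIF by tau0 (linear interpolation, zero before the grid start).
static std::vector<double> shift_aif(NumericVector aif, double dt,
                                     double tau0) {
  const int n = aif.size();
  std::vector<double> a(n);
  if (tau0 == 0.0) {
    for (int i = 0; i < n; ++i) a[i] = aif[i];
    return a;
  }
  for (int j = 0; j < n; ++j) {
    const double t = j * dt - tau0;
    if (t < 0.0) {
      a[j] = 0.0;
    } else {
      const double pos = t / dt;
      int k = (int)std::floor(pos);
      if (k >= n - 1) {
        a[j] = aif[n - 1];
      } else {
        const double w = pos - k;
        a[j] = (1.0 - w) * aif[k] + w * aif[k + 1];
      }
    }
  }
  return a;
}

// Tissue concentration curve C(t) = Fp (R * Ca(t - tau0)) on a uniform grid
// starting at t = 0 with spacing dt.
// [[Rcpp::export(name = ".cxm_curve_cpp")]]
NumericVector cxm_curve_cpp(NumericVector aif, double dt, double fb, double vp,
                            double ve, double ps, double tau0, double hct) {
  CxmExp e = cxm_exponents(fb, vp, ve, ps, hct);
  const double fp = fb / (1.0 - hct);
  const int n = aif.size();
  std::vector<double> a = shift_aif(aif, dt, tau0);
  std::vector<double> y(n, 0.0);
  if (e.degenerate) {
    const double th = (e.th1 + e.th2) / 2.0;
    const double slope = -fp / vp - th;
    conv_exp_linear(a, dt, fp, th, y);
    conv_texp_linear(a, dt, fp * slope, th, y);
  } else {
    conv_exp_linear(a, dt, fp * e.A, e.th1, y);
    conv_exp_linear(a, dt, fp * (1.0 - e.A), e.th2, y);
  }
  return NumericVector(y.begin(), y.end());
}

// Mean squared residual (1/N) sum (C_model - y)^2: the chi^2 cost of the fit.
// [[Rcpp::export(name = ".cxm_chi2_cpp")]]
double cxm_chi2_cpp(NumericVector aif, double dt, NumericVector yobs,
                    double fb, double vp, double ve, double ps, double tau0,
                    double hct) {
  NumericVector c = cxm_curve_cpp(aif, dt, fb, vp, ve, ps, tau0, hct);
  const int n = yobs.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double r = c[i] - yobs[i];
    s += r * r;
  }
  return s / n;
}

// Residual sum of squares (used by the Gaussian log-likelihood and the
// conjugate sigma^2 update).
// [[Rcpp::export(name = ".cxm_ssr_cpp")]]
double cxm_ssr_cpp(NumericVector aif, double dt, NumericVector yobs, double fb,
                   double vp, double ve, double ps, double tau0, double hct) {
  NumericVector c = cxm_curve_cpp(aif, dt, fb, vp, ve, ps, tau0, hct);
  const int n = yobs.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double r = c[i] - yobs[i];
    s += r * r;
  }
  return s;
}
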