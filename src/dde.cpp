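// Fixed-step RK4 integrator for DDE systems with constant discrete delays,
// using the method of steps. Delayed states are read from the stored
// solution with cubic Hermite interpolation between grid points; arguments
// at or before t0 come from the history function. A ring buffer holds the
// recent solution (state + derivative) back to the longest lag, so memory
// stays bounded even when stability forces very small steps (stiff
// fast-dimerization regime of the full model); the returned trajectory is
// thinned to `out_stride` grid points.
//
// Requiring dt <= min positive lag (enforced on the R side as lag/10) keeps
// every delayed stage argument inside the already-computed part of the
// solution, so no extrapolation is ever needed. Lags of exactly zero are
// served the current stage state.

#include <Rcpp.h>
#include <cmath>
#include <memory>
using namespace Rcpp;

namespace {

struct Ring {
  int dim, cap;
  long first;            // oldest step index still held
  long count;            // number of stored steps
  std::vector<double> y; // cap x dim
  std::vector<double> f; // cap x dim
  Ring(int dim_, int cap_) : dim(dim_), cap(cap_), first(0), count(0),
                             y((size_t)cap_ * dim_), f((size_t)cap_ * dim_) {}
  double *yrow(long i) { return &y[(size_t)(i % cap) * dim]; }
  double *frow(long i) { return &f[(size_t)(i % cap) * dim]; }
  void push(long i, const double *yi, const double *fi) {
    std::copy(yi, yi + dim, yrow(i));
    std::copy(fi, fi + dim, frow(i));
    if (count == 0) first = i;
    ++count;
    if (count > cap) { ++first; count = cap; }
  }
  void set_f(long i, const double *fi) { std::copy(fi, fi + dim, frow(i)); }
};

// Cubic Hermite on [t_j, t_{j+1}] at fraction theta.
inline void hermite(const double *y0, const double *f0, const double *y1,
                    const double *f1, double theta, double dt, int dim,
                    double *out) {
  const double t2 = theta * theta, t3 = t2 * theta;
  const double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
  const double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  for (int k = 0; k < dim; ++k)
    out[k] = h00 * y0[k] + dt * h10 * f0[k] + h01 * y1[k] + dt * h11 * f1[k];
}

class RhsBase {
public:
  virtual void eval(double t, const double *y, const double *const *lags,
                    double *dy) = 0;
  virtual ~RhsBase() {}
};

// Reduced three-variable clock model: monomers h1, h6, h7; equilibrium
// dimer levels are monomer products; repression is a single Hill term in
// d11 + d67 (threshold scaled to 1). Two delayed states: tau1 then tau7.
class MinimalRhs : public RhsBase {
  double k1, k6, k7, n, delta;
  bool homod2;
public:
  MinimalRhs(const NumericVector &p)
      : k1(p["kappa1"]), k6(p["kappa6"]), k7(p["kappa7"]), n(p["n"]),
        delta(p["delta"]), homod2(p["homod2"] != 0) {}
  void eval(double, const double *y, const double *const *lags, double *dy) {
    const double h1 = y[0], h6 = y[1], h7 = y[2];
    const double S = h1 + h6 + h7;
    const double d1 = lags[0][0] * lags[0][0] + lags[0][1] * lags[0][2];
    const double d7 = lags[1][0] * lags[1][0] + lags[1][1] * lags[1][2];
    const double r1 = 1.0 / (1.0 + std::pow(d1, n));
    const double r7 = 1.0 / (1.0 + std::pow(d7, n));
    const double l1 = homod2 ? h1 * (S + h1) : h1 * S;
    const double l6 = homod2 ? h6 * (S + h6) : h6 * S;
    const double l7 = homod2 ? h7 * (S + h7) : h7 * S;
    dy[0] = k1 * r1 - h1 - delta * l1;
    dy[1] = k6 - h6 - delta * l6;
    dy[2] = k7 * r7 - h7 - delta * l7;
  }
};

// Full mass-action model: h1, h6, h7, d11, d16, d17, d66, d67, d77.
// Repression reads the actual delayed dimer variables scaled by D0.
// Monomers decay at c, dimers at cdim (equal decay is the cdim == c case).
class FullRhs : public RhsBase {
  double k1, k6, k7, n, a, b, c, cdim, D0;
public:
  FullRhs(const NumericVector &p)
      : k1(p["kappa1"]), k6(p["kappa6"]), k7(p["kappa7"]), n(p["n"]),
        a(p["a"]), b(p["b"]), c(p["c"]), cdim(p["c_dim"]), D0(p["D0"]) {}
  void eval(double, const double *y, const double *const *lags, double *dy) {
    const double h1 = y[0], h6 = y[1], h7 = y[2];
    const double d11 = y[3], d16 = y[4], d17 = y[5], d66 = y[6], d67 = y[7],
                 d77 = y[8];
    const double rep1 = (lags[0][3] + lags[0][7]) / D0; // d11, d67 at s - tau1
    const double rep7 = (lags[1][3] + lags[1][7]) / D0; // d11, d67 at s - tau7
    const double r1 = 1.0 / (1.0 + std::pow(rep1, n));
    const double r7 = 1.0 / (1.0 + std::pow(rep7, n));
    dy[0] = k1 * r1 - c * h1 - 2 * a * h1 * h1 + 2 * b * d11 -
            a * h1 * h6 + b * d16 - a * h1 * h7 + b * d17;
    dy[1] = k6 - c * h6 - 2 * a * h6 * h6 + 2 * b * d66 - a * h1 * h6 +
            b * d16 - a * h6 * h7 + b * d67;
    dy[2] = k7 * r7 - c * h7 - 2 * a * h7 * h7 + 2 * b * d77 -
            a * h1 * h7 + b * d17 - a * h6 * h7 + b * d67;
    dy[3] = a * h1 * h1 - (b + cdim) * d11;
    dy[4] = a * h1 * h6 - (b + cdim) * d16;
    dy[5] = a * h1 * h7 - (b + cdim) * d17;
    dy[6] = a * h6 * h6 - (b + cdim) * d66;
    dy[7] = a * h6 * h7 - (b + cdim) * d67;
    dy[8] = a * h7 * h7 - (b + cdim) * d77;
  }
};

// Generic RHS given as an R function rhs(t, y, lags).
class RFunctionRhs : public RhsBase {
  Function fn;
  int dim, nlag;
public:
  RFunctionRhs(Function fn_, int dim_, int nlag_)
      : fn(fn_), dim(dim_), nlag(nlag_) {}
  void eval(double t, const double *y, const double *const *lags,
            double *dy) {
    NumericVector yv(y, y + dim);
    List lagl(nlag);
    for (int k = 0; k < nlag; ++k)
      lagl[k] = NumericVector(lags[k], lags[k] + dim);
    NumericVector out = fn(t, yv, lagl);
    if ((int)out.size() != dim)
      stop("rhs returned a vector of length %d; expected %d",
           (int)out.size(), dim);
    std::copy(out.begin(), out.end(), dy);
  }
};

} // namespace

// [[Rcpp::export(name = ".dde_rk4_cpp")]]
List dde_rk4_cpp(int model, SEXP rhs_fn, NumericVector params,
                 NumericVector delays, SEXP history, NumericVector y0,
                 double t0, double t_end, double dt, int out_stride,
                 bool clamp_nonneg) {
  const int dim = y0.size();
  const int nlag = delays.size();
  const long nsteps = (long)std::llround((t_end - t0) / dt);
  if (nsteps < 1) stop("t_end must exceed t0 by at least one step");

  std::unique_ptr<RhsBase> rhs;
  if (model == 1) rhs.reset(new MinimalRhs(params));
  else if (model == 2) rhs.reset(new FullRhs(params));
  else rhs.reset(new RFunctionRhs(Function(rhs_fn), dim, nlag));

  const bool hist_fun = Rf_isFunction(history);
  Function histf = hist_fun ? Function(history) : Function(Rf_findFun(
      Rf_install("identity"), R_GlobalEnv));
  NumericVector hist_const =
      hist_fun ? NumericVector(dim) : NumericVector(history);
  if (!hist_fun && (int)hist_const.size() != dim)
    stop("constant history must have length equal to the state dimension");

  double maxlag = 0.0;
  for (int k = 0; k < nlag; ++k) maxlag = std::max(maxlag, delays[k]);
  std::vector<long> lag_steps(nlag);
  for (int k = 0; k < nlag; ++k) lag_steps[k] = -1; // generic path

  const int cap = (int)std::ceil(maxlag / dt) + 3;
  Ring ring(dim, std::max(cap, 4));

  const long nout = nsteps / out_stride + 1;
  NumericVector times(nout);
  NumericMatrix states(nout, dim);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), ytmp(dim);
  std::vector<std::vector<double>> lagbuf(nlag, std::vector<double>(dim));
  std::vector<const double *> lagptr(nlag);

  long n_clamped = 0;
  long iout = 0;
  times[0] = t0;
  for (int k = 0; k < dim; ++k) states(0, k) = y[k];
  iout = 1;

  // delayed-state lookup at absolute time tq; stage state ystage serves
  // zero lags
  auto lookup = [&](double tq, const double *ystage, int k) {
    double *out = lagbuf[k].data();
    if (delays[k] == 0.0) {
      std::copy(ystage, ystage + dim, out);
      return;
    }
    if (tq <= t0 + 1e-12 * std::max(1.0, std::fabs(t0))) {
      if (hist_fun) {
        NumericVector hv = histf(tq);
        if ((int)hv.size() != dim)
          stop("history(t) must return a vector of length %d", dim);
        std::copy(hv.begin(), hv.end(), out);
      } else {
        std::copy(hist_const.begin(), hist_const.end(), out);
      }
      return;
    }
    const double u = (tq - t0) / dt;
    long j = (long)std::floor(u + 1e-9);
    double theta = u - j;
    if (theta < 1e-9) {
      std::copy(ring.yrow(j), ring.yrow(j) + dim, out);
      return;
    }
    if (j < ring.first)
      stop("internal error: delayed lookup fell behind the ring buffer");
    hermite(ring.yrow(j), ring.frow(j), ring.yrow(j + 1), ring.frow(j + 1),
            theta, dt, dim, out);
  };

  auto eval_rhs = [&](double t, const double *ystage, double *dy) {
    for (int k = 0; k < nlag; ++k) {
      lookup(t - delays[k], ystage, k);
      lagptr[k] = lagbuf[k].data();
    }
    rhs->eval(t, ystage, lagptr.data(), dy);
  };

  for (long i = 0; i < nsteps; ++i) {
    const double t = t0 + i * dt;
    // stage 1; stores f_i so Hermite patches ending at t_i are complete
    eval_rhs(t, y.data(), k1.data());
    ring.push(i, y.data(), k1.data());

    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + 0.5 * dt * k1[k];
    eval_rhs(t + 0.5 * dt, ytmp.data(), k2.data());
    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + 0.5 * dt * k2[k];
    eval_rhs(t + 0.5 * dt, ytmp.data(), k3.data());
    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + dt * k3[k];
    eval_rhs(t + dt, ytmp.data(), k4.data());

    bool bad = false;
    for (int k = 0; k < dim; ++k) {
      y[k] += dt / 6.0 * (k1[k] + 2 * k2[k] + 2 * k3[k] + k4[k]);
      if (!std::isfinite(y[k])) bad = true;
      if (clamp_nonneg && y[k] < 0) { y[k] = 0.0; ++n_clamped; }
    }
    if (bad)
      stop("non-finite state encountered at t = %g; reduce dt or check "
           "parameters", t + dt);

    if ((i + 1) % out_stride == 0 && iout < nout) {
      times[iout] = t0 + (i + 1) * dt;
      for (int k = 0; k < dim; ++k) states(iout, k) = y[k];
      ++iout;
    }
    if (model == 0 && i % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["states"] = states,
                      _["n_clamped"] = n_clamped);
}
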