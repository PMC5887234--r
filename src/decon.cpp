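#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tridiagonal (Thomas) solve: B x = b with bands (dl, d, du), no pivoting.
// B is strictly diagonally dominant for every operator built by this package,
// so plain elimination is stable.
// ---------------------------------------------------------------------------
static void thomas_solve(const double* dl, const double* d, const double* du,
                         const double* b, double* x, double* cp, double* dp,
                         int n) {
  cp[0] = du[0] / d[0];
  dp[0] = b[0] / d[0];
  for (int i = 1; i < n; ++i) {
    double m = d[i] - dl[i] * cp[i - 1];
    cp[i] = (i < n - 1) ? du[i] / m : 0.0;
    dp[i] = (b[i] - dl[i] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

// [[Rcpp::export]]
NumericVector cpp_tridiag_solve(NumericVector dl, NumericVector d,
                                NumericVector du, NumericVector b) {
  int n = d.size();
  NumericVector x(n);
  std::vector<double> cp(n), dp(n);
  thomas_solve(dl.begin(), d.begin(), du.begin(), b.begin(), x.begin(),
               cp.data(), dp.data(), n);
  return x;
}

// ---------------------------------------------------------------------------
// Same-size zero-padded convolution with an odd-length kernel centred at
// (K-1)/2, and its adjoint.  out = L x  or  out = L^t x.
// ---------------------------------------------------------------------------
static void conv_apply(const double* x, int n, const double* k, int K,
                       bool adjoint, double* out) {
  int c = (K - 1) / 2;
  // interior: kernel support fully inside the signal, no bounds checks
  int lo = c, hi = n - 1 - (K - 1 - c);
  if (adjoint) { lo = K - 1 - c; hi = n - 1 - c; }
  for (int i = lo; i <= hi; ++i) {
    double acc = 0.0;
    const double* xs = adjoint ? (x + i - c) : (x + i + c);
    if (adjoint)
      for (int j = 0; j < K; ++j) acc += k[j] * xs[j];
    else
      for (int j = 0; j < K; ++j) acc += k[j] * xs[-j];
    out[i] = acc;
  }
  for (int i = 0; i < n; ++i) {
    if (i >= lo && i <= hi) continue;
    double acc = 0.0;
    for (int j = 0; j < K; ++j) {
      int idx = adjoint ? (i + j - c) : (i - j + c);
      if (idx >= 0 && idx < n) acc += k[j] * x[idx];
    }
    out[i] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv(NumericVector x, NumericVector kernel, bool adjoint) {
  int n = x.size();
  NumericVector out(n);
  conv_apply(x.begin(), n, kernel.begin(), kernel.size(), adjoint, out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// A_mu v = v - B_mu^{-1} v applied through one Thomas solve.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_apply_A(NumericVector dl, NumericVector d, NumericVector du,
                          NumericVector v) {
  int n = d.size();
  NumericVector out(n);
  std::vector<double> cp(n), dp(n), sol(n);
  thomas_solve(dl.begin(), d.begin(), du.begin(), v.begin(), sol.data(),
               cp.data(), dp.data(), n);
  for (int i = 0; i < n; ++i) out[i] = v[i] - sol[i];
  return out;
}

// ---------------------------------------------------------------------------
// KKT-violation stopping criterion for bounds [l, u]: sum_i |s[i]| with the
// five-case componentwise definition (infeasible point -> +Inf).
// ---------------------------------------------------------------------------
static double kkt_violation_impl(const double* x, const double* g,
                                 const double* l, const double* u, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    if (x[i] < l[i] || x[i] > u[i])
      return std::numeric_limits<double>::infinity();
    if (l[i] == u[i]) continue;                 // pinned component
    if (x[i] == l[i]) s += std::fabs(std::min(0.0, g[i]));
    else if (x[i] == u[i]) s += std::fabs(std::max(0.0, g[i]));
    else s += std::fabs(g[i]);
  }
  return s;
}

// [[Rcpp::export]]
double cpp_kkt_violation(NumericVector x, NumericVector g, NumericVector l,
                         NumericVector u) {
  return kkt_violation_impl(x.begin(), g.begin(), l.begin(), u.begin(),
                            x.size());
}

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector x, NumericVector l, NumericVector u) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::min(u[i], std::max(l[i], x[i]));
  return out;
}

// ---------------------------------------------------------------------------
// Projected Barzilai-Borwein core.  The quadratic operator is abstracted so
// the deconvolution problems run natively while tests may pass any R closure.
// ---------------------------------------------------------------------------
struct ROp {
  Function f;
  explicit ROp(Function f_) : f(f_) {}
  void apply(const std::vector<double>& x, std::vector<double>& out) {
    NumericVector xv(x.begin(), x.end());
    NumericVector r = f(xv);
    std::copy(r.begin(), r.end(), out.begin());
  }
};

// Q v = lambda2 v + L^t A_mu L v  (A_mu from tridiagonal bands; empty bands
// mean A = I, i.e. the classical deconvolution operator Q = L^t L + lambda2 I)
struct DeconOp {
  const double* kern; int K;
  double lambda2;
  bool has_A;
  const double *dl, *d, *du;
  int n;
  std::vector<double> t1, t2, cp, dp;
  DeconOp(const double* kern_, int K_, double lambda2_, bool has_A_,
          const double* dl_, const double* d_, const double* du_, int n_)
      : kern(kern_), K(K_), lambda2(lambda2_), has_A(has_A_), dl(dl_), d(d_),
        du(du_), n(n_), t1(n_), t2(n_), cp(n_), dp(n_) {}
  void apply(const std::vector<double>& x, std::vector<double>& out) {
    conv_apply(x.data(), n, kern, K, false, t1.data());   // L x
    if (has_A) {
      thomas_solve(dl, d, du, t1.data(), t2.data(), cp.data(), dp.data(), n);
      for (int i = 0; i < n; ++i) t2[i] = t1[i] - t2[i];  // A L x
    } else {
      t2 = t1;
    }
    conv_apply(t2.data(), n, kern, K, true, out.data());  // L^t A L x
    for (int i = 0; i < n; ++i) out[i] += lambda2 * x[i];
  }
};

template <typename Op>
static List pbb_loop(Op& Q, const NumericVector& q, const NumericVector& l,
                     const NumericVector& u, const NumericVector& x0,
                     double tol, int max_iter, bool trace) {
  const int n = q.size();
  std::vector<double> x(n), g(n), Qx(n), xn(n), gn(n), Qg(n);
  for (int i = 0; i < n; ++i) x[i] = std::min(u[i], std::max(l[i], x0[i]));

  Q.apply(x, Qx);
  for (int i = 0; i < n; ++i) g[i] = Qx[i] + q[i];

  std::vector<double> obj;
  if (trace) obj.reserve(64);
  double kkt = kkt_violation_impl(x.data(), g.data(), l.begin(), u.begin(), n);
  bool converged = (kkt <= tol);
  int iter = 0;
  double bb1 = -1.0, bb2 = -1.0;  // <0 marks invalid

  auto objective = [&](const std::vector<double>& xv,
                       const std::vector<double>& gv) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xv[i] * (gv[i] + q[i]);
    return 0.5 * s;  // 1/2 x'(Qx + q) + 1/2 q'x = 1/2 x'Qx + q'x
  };
  if (trace) obj.push_back(objective(x, g));

  while (!converged && iter < max_iter) {
    ++iter;
    double alpha;
    double want_bb = (iter % 2 == 1) ? bb1 : bb2;  // alternate BB1 / BB2
    if (want_bb > 0.0) {
      alpha = want_bb;
    } else {  // first iteration or degenerate BB step: Cauchy step
      Q.apply(g, Qg);
      double gg = 0.0, gQg = 0.0;
      for (int i = 0; i < n; ++i) { gg += g[i] * g[i]; gQg += g[i] * Qg[i]; }
      alpha = (gQg > 0.0 && std::isfinite(gQg)) ? gg / gQg : 1.0;
    }
    for (int i = 0; i < n; ++i)
      xn[i] = std::min(u[i], std::max(l[i], x[i] - alpha * g[i]));
    Q.apply(xn, Qx);
    for (int i = 0; i < n; ++i) gn[i] = Qx[i] + q[i];

    double dxdx = 0.0, dxdg = 0.0, dgdg = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = xn[i] - x[i], dg = gn[i] - g[i];
      dxdx += dx * dx; dxdg += dx * dg; dgdg += dg * dg;
    }
    auto valid = [](double a) {
      return std::isfinite(a) && a > 1e-12 && a < 1e12;
    };
    bb1 = (dxdg > 1e-300) ? dxdx / dxdg : -1.0;
    bb2 = (dgdg > 1e-300) ? dxdg / dgdg : -1.0;
    if (!valid(bb1)) bb1 = -1.0;
    if (!valid(bb2)) bb2 = -1.0;

    x.swap(xn); g.swap(gn);
    if (trace) obj.push_back(objective(x, g));
    kkt = kkt_violation_impl(x.data(), g.data(), l.begin(), u.begin(), n);
    converged = (kkt <= tol);
  }

  return List::create(
      _["solution"] = NumericVector(x.begin(), x.end()),
      _["iterations"] = iter, _["kkt_residual"] = kkt,
      _["objective_trace"] =
          trace ? NumericVector(obj.begin(), obj.end()) : NumericVector(0),
      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpp_pbb_r(Function apply_Q, NumericVector q, NumericVector l,
               NumericVector u, NumericVector x0, double tol, int max_iter,
               bool trace) {
  ROp op(apply_Q);
  return pbb_loop(op, q, l, u, x0, tol, max_iter, trace);
}

// [[Rcpp::export]]
List cpp_pbb_decon(NumericVector kernel, double lambda2, NumericVector dl,
                   NumericVector d, NumericVector du, NumericVector q,
                   NumericVector l, NumericVector u, NumericVector x0,
                   double tol, int max_iter, bool trace) {
  bool has_A = d.size() > 0;
  DeconOp op(kernel.begin(), kernel.size(), lambda2, has_A, dl.begin(),
             d.begin(), du.begin(), q.size());
  return pbb_loop(op, q, l, u, x0, tol, max_iter, trace);
}
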