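// Fixed-step RK4 integration of the bilinear neural model coupled to the
// balloon hemodynamic model, with sparse sampling of the predicted BOLD
// signal.  Hemodynamic states (f, v, q) are integrated in log space so they
// stay positive; the neural state and the vasodilatory signal are linear.
//
// Inputs u are piecewise constant on the integration grid; the effective
// coupling matrix (off-diagonal A + sum_j u_j B_j; diagonal
// -0.5 * exp(a_ii + sum_j u_j b_j,ii)) is recomputed only when u changes,
// which makes boxcar designs cheap.  Per-region hemodynamic constants are
// cached in plain arrays: this routine sits inside the finite-difference
// Jacobian of the model inversion and is called hundreds of times per
// Gauss-Newton iteration.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct HemoConst {
  double kappa, gamma, inv_tau, inv_alpha, E0, inv_E0, log1mE0;
};

// state layout: [z_1..z_n, s_1..s_n, lf_1..lf_n, lv_1..lv_n, lq_1..lq_n]
static inline void dcm_deriv(const double* __restrict x,
                             double* __restrict dx,
                             const double* __restrict Aeff,
                             const double* __restrict Cu,
                             const HemoConst* __restrict hc, int nreg) {
  const double* z = x;
  const double* s = x + nreg;
  const double* lf = x + 2 * nreg;
  const double* lv = x + 3 * nreg;
  const double* lq = x + 4 * nreg;
  for (int i = 0; i < nreg; ++i) {
    double dz = Cu[i];
    for (int j = 0; j < nreg; ++j) dz += Aeff[i + j * nreg] * z[j];
    dx[i] = dz;
  }
  for (int i = 0; i < nreg; ++i) {
    const HemoConst& h = hc[i];
    const double f = std::exp(lf[i]);
    const double inv_f = 1.0 / f;
    const double fv_over_v = std::exp(lv[i] * (h.inv_alpha - 1.0));
    const double Ef = 1.0 - std::exp(h.log1mE0 * inv_f);
    dx[nreg + i] = z[i] - h.kappa * s[i] - h.gamma * (f - 1.0);
    dx[2 * nreg + i] = s[i] * inv_f;
    dx[3 * nreg + i] = (f * std::exp(-lv[i]) - fv_over_v) * h.inv_tau;
    dx[4 * nreg + i] =
        (f * Ef * h.inv_E0 * std::exp(-lq[i]) - fv_over_v) * h.inv_tau;
  }
}

// [[Rcpp::export]]
NumericMatrix dcm_integrate_cpp(NumericMatrix A, List Bs, NumericMatrix Cmat,
                                NumericMatrix u, NumericMatrix hemo,
                                double dt, IntegerVector sample_steps,
                                double te) {
  const int nreg = A.nrow();
  const int m = u.nrow();
  const int nT = u.ncol();
  const int ns = 5 * nreg;
  if (Bs.size() != m) stop("need one modulation matrix per input");
  if (Cmat.nrow() != nreg || Cmat.ncol() != m) stop("C has wrong shape");
  if (hemo.nrow() != nreg || hemo.ncol() < 7) stop("hemo has wrong shape");

  std::vector<const double*> Bp(m);
  std::vector<NumericMatrix> keep;   // protect from GC
  bool any_B = false;
  for (int k = 0; k < m; ++k) {
    NumericMatrix Bk = Bs[k];
    if (Bk.nrow() != nreg || Bk.ncol() != nreg) stop("B has wrong shape");
    keep.push_back(Bk);
    Bp[k] = REAL(Bk);
    for (int q = 0; q < nreg * nreg; ++q)
      if (Bp[k][q] != 0.0) { any_B = true; break; }
  }
  const double* Ap = REAL(A);
  const double* Cp = REAL(Cmat);
  const double* up = REAL(u);

  std::vector<HemoConst> hc(nreg);
  std::vector<double> kc1(nreg), kc2(nreg), kc3(nreg), V0(nreg);
  for (int i = 0; i < nreg; ++i) {
    const double E0 = hemo(i, 4), eps = hemo(i, 6);
    hc[i].kappa = hemo(i, 0);
    hc[i].gamma = hemo(i, 1);
    hc[i].inv_tau = 1.0 / hemo(i, 2);
    hc[i].inv_alpha = 1.0 / hemo(i, 3);
    hc[i].E0 = E0;
    hc[i].inv_E0 = 1.0 / E0;
    hc[i].log1mE0 = std::log1p(-E0);
    V0[i] = hemo(i, 5);
    kc1[i] = 4.3 * 40.3 * E0 * te;
    kc2[i] = eps * 25.0 * E0 * te;
    kc3[i] = 1.0 - eps;
  }

  std::vector<double> x(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), xt(ns);
  std::vector<double> Aeff(nreg * nreg), Cu(nreg),
      ucur(m, std::numeric_limits<double>::quiet_NaN());

  const int nsamp = sample_steps.size();
  NumericMatrix Y(nsamp, nreg);
  int isamp = 0;

  auto recompute_coupling = [&]() {
    for (int j = 0; j < nreg; ++j) {
      for (int i = 0; i < nreg; ++i) {
        double a = Ap[i + j * nreg];
        if (any_B)
          for (int k = 0; k < m; ++k) a += ucur[k] * Bp[k][i + j * nreg];
        Aeff[i + j * nreg] = (i == j) ? -0.5 * std::exp(a) : a;
      }
    }
    for (int i = 0; i < nreg; ++i) {
      double ci = 0.0;
      for (int k = 0; k < m; ++k) ci += Cp[i + k * nreg] * ucur[k];
      Cu[i] = ci;
    }
  };

  auto record = [&](int row) {
    for (int i = 0; i < nreg; ++i) {
      const double v = std::exp(x[3 * nreg + i]);
      const double q = std::exp(x[4 * nreg + i]);
      Y(row, i) = 100.0 * V0[i] *
          (kc1[i] * (1.0 - q) + kc2[i] * (1.0 - q / v) + kc3[i] * (1.0 - v));
    }
  };

  // sample step 0 = initial rest state
  while (isamp < nsamp && sample_steps[isamp] == 0) record(isamp++);

  const double dt2 = 0.5 * dt, dt6 = dt / 6.0;
  for (int step = 0; step < nT; ++step) {
    const double* ustep = up + (std::size_t)step * m;
    bool changed = false;
    for (int k = 0; k < m; ++k)
      if (ustep[k] != ucur[k]) { changed = true; break; }
    if (changed) {
      for (int k = 0; k < m; ++k) ucur[k] = ustep[k];
      recompute_coupling();
    }
    dcm_deriv(x.data(), k1.data(), Aeff.data(), Cu.data(), hc.data(), nreg);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + dt2 * k1[i];
    dcm_deriv(xt.data(), k2.data(), Aeff.data(), Cu.data(), hc.data(), nreg);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + dt2 * k2[i];
    dcm_deriv(xt.data(), k3.data(), Aeff.data(), Cu.data(), hc.data(), nreg);
    for (int i = 0; i < ns; ++i) xt[i] = x[i] + dt * k3[i];
    dcm_deriv(xt.data(), k4.data(), Aeff.data(), Cu.data(), hc.data(), nreg);
    double norm = 0.0;
    for (int i = 0; i < ns; ++i) {
      x[i] += dt6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
      norm += x[i] * x[i];
    }
    if (!std::isfinite(norm) || norm > 1e12)
      stop("unstable integration: state norm diverged at t = %f s "
           "(check self-connections and input scaling)",
           (step + 1) * dt);
    while (isamp < nsamp && sample_steps[isamp] == step + 1) record(isamp++);
  }
  if (isamp < nsamp) stop("sample steps beyond the input grid");
  return Y;
}
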