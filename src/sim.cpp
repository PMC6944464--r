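// Coupled low-order ventricle / circulation integrator.
//
// State layout: [A_1..A_n, F_1..F_n, V, Pwk, Pat] integrated with fixed-step
// RK4. Pressure is eliminated algebraically: for the single-element and
// parallel configurations P follows directly from the passive law plus the
// (quadrature-averaged) active tension; for the series configuration a nested
// Newton solve partitions the total volume across subunits under a common
// pressure at every stage evaluation.
//
// Units: kPa, ml, ms internally. Resistances arrive in kPa ml^-1 s and rates
// in 1/s; flows are computed in ml/s and scaled by 1e-3 where they enter
// ml/ms state derivatives.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  // mode: 0 = single/parallel (per-subunit mu1), 1 = series (per-subunit w)
  int mode;
  int n;
  std::vector<double> mu1s; // parallel: per-subunit mu1
  std::vector<double> w;    // series: per-subunit weight
  double mu1, mu2, gam, alpha, beta, a, b, c, V0;
  double fXB, gXB, n0, nA, Sa, tau1, tau2, Ca_d, Ca_amp, Ca50, k_on, k_off,
      t_act;          // rates per ms, times ms
  double ca_norm;     // biexponential peak normalization
  double Pat0, Cat, Rmv, R1, R2, R3, Cwk; // kPa ml^-1 s, ml/kPa
  bool capacitor;
  bool weight_beta;

  // warm-start caches for the series partition
  mutable std::vector<double> Vsub;
  mutable double Pcommon;
  mutable double max_resid;

  double calcium(double tl) const {
    double s = tl - t_act;
    if (s < 0) return Ca_d;
    return Ca_d + Ca_amp * ca_norm * (std::exp(-s / tau2) - std::exp(-s / tau1));
  }

  double hill(double ca) const {
    if (ca <= 0) return 0.0;
    double r = std::pow(ca / Ca50, nA);
    return r / (1.0 + r);
  }

  double lenfac(double lam) const {
    return lam > n0 ? (lam - n0) / (1.0 - n0) : 0.0;
  }

  double passive(double V, double al, double bg, double aa, double bb,
                 double cc) const {
    double x = V / V0 - 1.0;
    if (x <= 0) return al * (1.0 - std::exp(-bg * x));
    return ((aa * x + bb) * x + cc) * x;
  }

  double dpassive(double V, double al, double bg, double aa, double bb,
                  double cc) const {
    double x = V / V0 - 1.0;
    if (x <= 0) return al * bg * std::exp(-bg * x) / V0;
    return (3.0 * aa * x * x + 2.0 * bb * x + cc) / V0;
  }

  // series subunit pressure map and slope at volume Vi
  double subP(double Vi, int i, const double* F) const {
    double wi = w[i];
    double bg = (weight_beta ? beta * wi : beta) * gam;
    double p = passive(Vi, alpha * wi, bg, a * wi, b * wi, c * wi);
    double lam = mu1 * (Vi / V0 - 1.0) + 1.0;
    return p + mu2 * wi * Sa * F[i] * lenfac(lam);
  }
  double dsubP(double Vi, int i, const double* F) const {
    double wi = w[i];
    double bg = (weight_beta ? beta * wi : beta) * gam;
    double d = dpassive(Vi, alpha * wi, bg, a * wi, b * wi, c * wi);
    double lam = mu1 * (Vi / V0 - 1.0) + 1.0;
    if (lam > n0) d += mu2 * wi * Sa * F[i] * (mu1 / V0) / (1.0 - n0);
    return d;
  }

  // invert subP(.,i) = P with Newton safeguarded by a bracket
  double invert_sub(double P, int i, double guess, const double* F) const {
    double lo = guess, hi = guess;
    double flo = subP(lo, i, F) - P;
    double fhi = flo;
    int guard = 0;
    while (flo > 0 && guard++ < 200) { lo *= 0.7; flo = subP(lo, i, F) - P; }
    guard = 0;
    while (fhi < 0 && guard++ < 200) { hi *= 1.4; fhi = subP(hi, i, F) - P; }
    double Vi = std::min(std::max(guess, lo), hi);
    for (int it = 0; it < 100; ++it) {
      double f = subP(Vi, i, F) - P;
      if (std::fabs(f) < 1e-11) return Vi;
      if (f > 0) hi = Vi; else lo = Vi;
      double d = dsubP(Vi, i, F);
      double Vn = (d > 0) ? Vi - f / d : 0.5 * (lo + hi);
      if (Vn <= lo || Vn >= hi) Vn = 0.5 * (lo + hi);
      Vi = Vn;
    }
    return Vi;
  }

  // series: common P and subunit volumes with mean(Vsub) = V.
  // Joint Newton iteration, warm-started from the previous evaluation: each
  // pass applies one Newton update per subunit toward subP(Vi) = P, then one
  // Newton update of P toward mean(Vi) = V; near the warm start the coupled
  // system is almost linear and a handful of passes reach ~1e-12 residuals.
  double partition(double V, const double* F) const {
    double P = Pcommon;
    double r_p = 0.0;
    bool ok = false;
    for (int it = 0; it < 60; ++it) {
      double sum = 0.0, dsum = 0.0;
      r_p = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = dsubP(Vsub[i], i, F);
        double f = subP(Vsub[i], i, F) - P;
        double Vn = Vsub[i] - f / d;
        if (!(Vn > 0.05 * V0) || !(Vn < 50.0 * V0) || !std::isfinite(Vn))
          Vn = invert_sub(P, i, Vsub[i], F); // safeguarded fallback
        Vsub[i] = Vn;
        r_p = std::max(r_p, std::fabs(f));
        sum += Vn;
        dsum += 1.0 / dsubP(Vn, i, F);
      }
      double g = sum / n - V;
      P -= g / (dsum / n);
      if (std::fabs(g) < 1e-12 && r_p < 1e-11) { ok = true; break; }
    }
    if (!ok && r_p > 1e-11) P = partition_bracketed(V, F, r_p);
    Pcommon = P;
    if (r_p > max_resid) max_resid = r_p;
    return P;
  }

  // cold-start-safe solve: fully converged subunit inversions inside a
  // bisection/Newton hybrid on the common pressure
  double partition_bracketed(double V, const double* F, double& r_p) const {
    for (int i = 0; i < n; ++i) Vsub[i] = V;
    double P = 0.0;
    for (int i = 0; i < n; ++i) P += subP(V, i, F);
    P /= n;
    double g_of = 0.0;
    auto g = [&](double Pq) {
      double sum = 0.0;
      for (int i = 0; i < n; ++i) {
        Vsub[i] = invert_sub(Pq, i, Vsub[i], F);
        sum += Vsub[i];
      }
      return sum / n - V;
    };
    double lo = P, hi = P, glo = g(P), ghi = glo;
    int guard = 0;
    while (glo > 0 && guard++ < 200) { lo -= std::max(1.0, std::fabs(lo)); glo = g(lo); }
    guard = 0;
    while (ghi < 0 && guard++ < 200) { hi += std::max(1.0, std::fabs(hi)); ghi = g(hi); }
    for (int it = 0; it < 200; ++it) {
      P = 0.5 * (lo + hi);
      g_of = g(P);
      if (std::fabs(g_of) < 1e-12 || hi - lo < 1e-14 * std::max(1.0, std::fabs(P)))
        break;
      if (g_of > 0) hi = P; else lo = P;
    }
    r_p = 0.0;
    for (int i = 0; i < n; ++i)
      r_p = std::max(r_p, std::fabs(subP(Vsub[i], i, F) - P));
    return P;
  }

  // algebraic LV pressure given volume and crossbridge fractions
  double pressure(double V, const double* F) const {
    if (mode == 1) return partition(V, F);
    double tbar = 0.0;
    for (int i = 0; i < n; ++i) {
      double lam = mu1s[i] * (V / V0 - 1.0) + 1.0;
      tbar += Sa * F[i] * lenfac(lam);
    }
    tbar /= n;
    return mu2 * tbar + passive(V, alpha, beta * gam, a, b, c);
  }

  void deriv(double tl, const std::vector<double>& y,
             std::vector<double>& dy) const {
    const double* A = y.data();
    const double* F = y.data() + n;
    double V = y[2 * n], Pwk = y[2 * n + 1], Pat = y[2 * n + 2];
    double P = pressure(V, F);
    double Qmv = Pat > P ? (Pat - P) / Rmv : 0.0;  // ml/s
    double Qao = P > Pwk ? (P - Pwk) / (R1 + R2) : 0.0;
    double ca = calcium(tl);
    double H = hill(ca);
    double kf = k_on * H;
    for (int i = 0; i < n; ++i) {
      dy[i] = kf * (1.0 - A[i]) - k_off * A[i];
      dy[n + i] = fXB * A[i] * (1.0 - F[i]) - gXB * F[i];
    }
    dy[2 * n] = (Qmv - Qao) * 1e-3;                  // ml/ms
    dy[2 * n + 1] = (Qao - Pwk / R3) / Cwk * 1e-3;   // kPa/ms
    dy[2 * n + 2] = capacitor ? -Qmv / Cat * 1e-3 : 0.0;
  }
};

} // namespace

// [[Rcpp::export]]
List sim_lv_cpp(int mode, NumericVector mu1_sub, NumericVector w_sub,
                double mu1, double mu2, double gam, double alpha, double beta,
                double a, double b, double c, double V0, double fXB,
                double gXB, double n0, double nA, double Sa, double tau1,
                double tau2, double Ca_d, double Ca_amp, double Ca50,
                double k_on, double k_off, double t_act, double Pat0,
                bool atrium_capacitor, double Cat, double Rmv, double R1,
                double R2, double R3, double Cwk, double period,
                int max_beats, double dt, double dt_out, double ss_tol,
                bool weight_beta, bool return_subunits) {
  Model m;
  m.mode = mode;
  m.n = (mode == 1) ? w_sub.size() : mu1_sub.size();
  m.mu1s.assign(mu1_sub.begin(), mu1_sub.end());
  m.w.assign(w_sub.begin(), w_sub.end());
  m.mu1 = mu1; m.mu2 = mu2; m.gam = gam; m.alpha = alpha; m.beta = beta;
  m.a = a; m.b = b; m.c = c; m.V0 = V0;
  m.fXB = fXB / 1000.0; m.gXB = gXB / 1000.0;
  m.n0 = n0; m.nA = nA; m.Sa = Sa;
  m.tau1 = tau1; m.tau2 = tau2; m.Ca_d = Ca_d; m.Ca_amp = Ca_amp;
  m.Ca50 = Ca50; m.k_on = k_on / 1000.0; m.k_off = k_off / 1000.0;
  m.t_act = t_act;
  double speak = tau1 * tau2 / (tau2 - tau1) * std::log(tau2 / tau1);
  m.ca_norm = 1.0 / (std::exp(-speak / tau2) - std::exp(-speak / tau1));
  m.Pat0 = Pat0; m.Cat = Cat; m.Rmv = Rmv; m.R1 = R1; m.R2 = R2; m.R3 = R3;
  m.Cwk = Cwk; m.capacitor = atrium_capacitor; m.weight_beta = weight_beta;
  m.max_resid = 0.0;

  int n = m.n;
  int steps = (int)std::lround(period / dt);
  if (std::fabs(steps * dt - period) > 1e-9)
    stop("dt must divide the pacing period exactly");
  int out_every = (int)std::lround(dt_out / dt);
  if (out_every < 1 || std::fabs(out_every * dt - dt_out) > 1e-9)
    stop("dt_out must be a multiple of dt");
  int n_out = steps / out_every + 1;

  std::vector<double> y(2 * n + 3, 0.0), dy(2 * n + 3), yt(2 * n + 3),
      k1(2 * n + 3), k2(2 * n + 3), k3(2 * n + 3), k4(2 * n + 3);
  y[2 * n] = V0;
  y[2 * n + 1] = Pat0;
  y[2 * n + 2] = Pat0;
  m.Vsub.assign(n, V0);
  m.Pcommon = 0.0;

  NumericVector t_out(n_out), P_out(n_out), V_out(n_out), Pao_out(n_out),
      Qmv_out(n_out), Qao_out(n_out), lam_out(n_out), Pat_out(n_out),
      Pwk_out(n_out);
  NumericMatrix Vsub_out = return_subunits ? NumericMatrix(n_out, n)
                                           : NumericMatrix(0, 0);
  std::vector<double> edv_hist, pwk_hist;
  bool converged = false;
  int beats_run = 0;

  auto record = [&](int idx, double tl) {
    const double* F = y.data() + n;
    double V = y[2 * n], Pwk = y[2 * n + 1], Pat = y[2 * n + 2];
    double P = m.pressure(V, F);
    double Qmv = Pat > P ? (Pat - P) / m.Rmv : 0.0;
    double Qao = P > Pwk ? (P - Pwk) / (m.R1 + m.R2) : 0.0;
    t_out[idx] = tl;
    P_out[idx] = P;
    V_out[idx] = V;
    Pao_out[idx] = Pwk + Qao * m.R2;
    Qmv_out[idx] = Qmv;
    Qao_out[idx] = Qao;
    Pat_out[idx] = Pat;
    Pwk_out[idx] = Pwk;
    double lbar = 0.0;
    if (m.mode == 1) {
      for (int i = 0; i < n; ++i)
        lbar += m.mu1 * (m.Vsub[i] / m.V0 - 1.0) + 1.0;
      if (return_subunits)
        for (int i = 0; i < n; ++i) Vsub_out(idx, i) = m.Vsub[i];
    } else {
      for (int i = 0; i < n; ++i)
        lbar += m.mu1s[i] * (V / m.V0 - 1.0) + 1.0;
    }
    lam_out[idx] = lbar / n;
  };

  for (int beat = 0; beat < max_beats; ++beat) {
    if (m.capacitor) y[2 * n + 2] = Pat0; // atrial recharge at cycle start
    record(0, 0.0);
    for (int s = 0; s < steps; ++s) {
      double tl = s * dt;
      m.deriv(tl, y, k1);
      for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + 0.5 * dt * k1[j];
      m.deriv(tl + 0.5 * dt, yt, k2);
      for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + 0.5 * dt * k2[j];
      m.deriv(tl + 0.5 * dt, yt, k3);
      for (size_t j = 0; j < y.size(); ++j) yt[j] = y[j] + dt * k3[j];
      m.deriv(tl + dt, yt, k4);
      for (size_t j = 0; j < y.size(); ++j)
        y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(y[2 * n]) || y[2 * n] <= 0 ||
          !std::isfinite(y[0]) || !std::isfinite(y[n]) ||
          !std::isfinite(y[2 * n + 1]))
        stop("simulation failure: non-finite or non-physical state at beat "
             "%d, t = %.2f ms", beat + 1, tl + dt);
      if ((s + 1) % out_every == 0) {
        record((s + 1) / out_every, tl + dt);
        if (!std::isfinite(P_out[(s + 1) / out_every]))
          stop("simulation failure: non-finite pressure at beat %d, "
               "t = %.2f ms", beat + 1, tl + dt);
      }
    }
    beats_run = beat + 1;
    edv_hist.push_back(y[2 * n]);
    pwk_hist.push_back(y[2 * n + 1]);
    if (beat > 0) {
      // cycle-to-cycle stability of both the end-diastolic volume and the
      // Windkessel pressure (the slowest state, time constant R3*Cwk)
      double rel_v = std::fabs(edv_hist[beat] - edv_hist[beat - 1]) /
                     edv_hist[beat - 1];
      double rel_p = std::fabs(pwk_hist[beat] - pwk_hist[beat - 1]) /
                     std::max(pwk_hist[beat - 1], 1e-6);
      if (rel_v < ss_tol && rel_p < ss_tol) { converged = true; break; }
    }
  }

  List out = List::create(
      _["t"] = t_out, _["P"] = P_out, _["V"] = V_out, _["Pao"] = Pao_out,
      _["Qmv"] = Qmv_out, _["Qao"] = Qao_out, _["lambda"] = lam_out,
      _["Pat"] = Pat_out, _["Pwk"] = Pwk_out, _["beats_run"] = beats_run,
      _["converged"] = converged,
      _["edv_history"] = NumericVector(edv_hist.begin(), edv_hist.end()),
      _["partition_residual"] = m.max_resid);
  if (return_subunits) out["Vsub"] = Vsub_out;
  return out;
}

// Series volume partition exposed for direct calls and cross-checks.
// [[Rcpp::export]]
List partition_cpp(double V_total, NumericVector F, NumericVector w_sub,
                   double mu1, double mu2, double gam, double alpha,
                   double beta, double a, double b, double c, double V0,
                   double n0, double Sa, bool weight_beta,
                   NumericVector V_guess, double P_guess) {
  Model m;
  m.mode = 1;
  m.n = w_sub.size();
  m.w.assign(w_sub.begin(), w_sub.end());
  m.mu1 = mu1; m.mu2 = mu2; m.gam = gam; m.alpha = alpha; m.beta = beta;
  m.a = a; m.b = b; m.c = c; m.V0 = V0; m.n0 = n0; m.Sa = Sa;
  m.weight_beta = weight_beta;
  m.max_resid = 0.0;
  m.Vsub.assign(V_guess.begin(), V_guess.end());
  m.Pcommon = P_guess;
  double P = m.partition(V_total, F.begin());
  return List::create(_["P"] = P,
                      _["V_sub"] = NumericVector(m.Vsub.begin(), m.Vsub.end()),
                      _["residual"] = m.max_resid);
}
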