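#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-subject machinery for the first-order conditional (FOCE) marginal
// likelihood of the one-compartment trough model with log-additive
// residual error:
//
//   ln C_obs_j = c0 - eta1 + ln Ac_j(u) + eps_j,   u = eta2 - eta1,
//
// where Ac_j is the central-compartment amount propagated over the event
// schedule with per-event typical elimination rate ke0 (covariates folded
// in) scaled by e^u, and c0 = ln(1000 / theta_V).  The conditional mode
// eta-hat is found by Gauss-Newton with step halving; the subject's
// -2 log marginal-likelihood contribution uses the first-order expansion
// of the model about eta-hat.
//
// Consecutive identical (dt, ke) segments (a twice-daily dose train) reuse
// their exponentials, so regular dosing costs O(1) exp per interval.

namespace {

struct SubjectResult {
  double ofv;
  double eta1, eta2;
  std::vector<double> lnc;
  std::vector<double> G1, G2;
  bool converged, prior_only, ok;
};

// Segment coefficients for a step of length dt at elimination rate ke.
struct Seg { double Ea, Ee, B, dB; };

inline Seg seg_coef(double ka, double ke, double dt) {
  Seg s;
  s.Ea = std::exp(-ka * dt);
  if (std::fabs(ka - ke) > 1e-8 * ka) {
    s.Ee = std::exp(-ke * dt);
    const double f = (s.Ee - s.Ea) / (ka - ke);
    s.B = ka * f;
    s.dB = ke * (ka * f / (ka - ke) - ka / (ka - ke) * dt * s.Ee);
  } else {
    s.Ee = s.Ea;
    s.B = ka * dt * s.Ea;
    s.dB = ke * (-0.5 * ka * dt * dt * s.Ea);
  }
  return s;
}

// Events may be dose trains: ev_n equally spaced (ev_tau) doses of ev_amt
// each, starting at ev_time; the whole train is advanced by geometric
// accumulation so a regular BID interval costs O(1).
bool propagate(const double *ev_time, const double *ev_amt,
               const int *ev_obs, const int *ev_n, const double *ev_tau,
               const double *ke0, int n,
               double ka, double u, bool grad,
               std::vector<double> &Ac_out, std::vector<double> &S_out) {
  bool ok = true;
  double Ag = 0.0, Ac = 0.0, S = 0.0;
  double tcur = (n > 0) ? ev_time[0] : 0.0;
  const double eu = std::exp(u);
  double dt_last = -1.0, ke_last = -1.0;
  Seg sg = {0, 0, 0, 0};
  Ac_out.clear(); S_out.clear();
  for (int i = 0; i < n; ++i) {
    const double dt = ev_time[i] - tcur;
    const double ke = ke0[i] * eu;
    if (dt > 0.0) {
      if (dt != dt_last || ke != ke_last) {
        sg = seg_coef(ka, ke, dt);
        dt_last = dt; ke_last = ke;
      }
      const double Ac_new = Ac * sg.Ee + Ag * sg.B;
      if (grad) S = S * sg.Ee + Ac * (-dt * ke * sg.Ee) + Ag * sg.dB;
      Ac = Ac_new;
      Ag *= sg.Ea;
      tcur = ev_time[i];
    }
    if (ev_obs[i]) {
      if (!(Ac > 0.0) || !std::isfinite(Ac)) ok = false;
      Ac_out.push_back(Ac);
      S_out.push_back(S);
    }
    if (ev_amt[i] > 0.0) {
      const int m = ev_n[i] - 1;
      const double A = ev_amt[i];
      if (m <= 0) {
        Ag += A;
      } else {
        const double tau = ev_tau[i];
        if (std::fabs(ka - ke) <= 1e-8 * ka) {
          // degenerate ka ~= ke: step the train dose by dose
          Seg st = seg_coef(ka, ke, tau);
          Ag += A;
          for (int j = 0; j < m; ++j) {
            const double Ac_new = Ac * st.Ee + Ag * st.B;
            if (grad) S = S * st.Ee + Ac * (-tau * ke * st.Ee) + Ag * st.dB;
            Ac = Ac_new;
            Ag = Ag * st.Ea + A;
          }
        } else {
          Seg st = seg_coef(ka, ke, tau);
          const double qe = st.Ee, qa = st.Ea;
          const double P = std::pow(qe, m), qam = std::pow(qa, m);
          const double cc = A / (1.0 - qa);
          const double alpha = Ag + A - cc;
          const double T1 = alpha * (P - qam) / (qe - qa);
          const double T2 = cc * (1.0 - P) / (1.0 - qe);
          const double Ac_new = Ac * P + st.B * (T1 + T2);
          if (grad) {
            const double dP = -ke * tau * m * P;
            const double dqe = -ke * tau * qe;
            const double dT1 = alpha *
              (dP * (qe - qa) - (P - qam) * dqe) / ((qe - qa) * (qe - qa));
            const double dT2 = cc *
              (-dP * (1.0 - qe) + (1.0 - P) * dqe) /
              ((1.0 - qe) * (1.0 - qe));
            S = S * P + Ac * dP + st.dB * (T1 + T2) + st.B * (dT1 + dT2);
          }
          Ac = Ac_new;
          Ag = Ag * qam + A * (1.0 - std::pow(qa, m + 1)) / (1.0 - qa);
        }
        tcur = ev_time[i] + m * tau;
        dt_last = -1.0;  // force recomputation after the train
      }
    }
  }
  return ok;
}

SubjectResult foce_one(const double *ev_time, const double *ev_amt,
                       const int *ev_obs, const int *ev_n,
                       const double *ev_tau, const double *ke0, int nev,
                       const double *lobs, int nobs,
                       double ka, double c0, double sigma2,
                       const double *omega2, const double *eta_start,
                       int maxit, double gtol) {
  SubjectResult out;
  out.converged = false; out.prior_only = false; out.ok = true;
  const bool f1 = omega2[0] > 0.0, f2 = omega2[1] > 0.0;
  double e1 = f1 ? eta_start[0] : 0.0, e2 = f2 ? eta_start[1] : 0.0;
  const double oi1 = f1 ? 1.0 / omega2[0] : 0.0;
  const double oi2 = f2 ? 1.0 / omega2[1] : 0.0;

  if (nobs == 0) {
    out.ofv = 0.0; out.eta1 = 0.0; out.eta2 = 0.0;
    out.converged = true; out.prior_only = true;
    return out;
  }

  std::vector<double> Ac, S, Ac_t, S_t;
  std::vector<double> lnc(nobs), r(nobs), g(nobs);
  double h = 0.0;

  auto fill = [&](double eta1, double eta2, const std::vector<double> &A,
                  const std::vector<double> &Sv) {
    double hval = oi1 * eta1 * eta1 + oi2 * eta2 * eta2;
    for (int j = 0; j < nobs; ++j) {
      const double lc = c0 - eta1 + std::log(A[j]);
      const double rj = lobs[j] - lc;
      hval += rj * rj / sigma2;
      lnc[j] = lc; r[j] = rj; g[j] = Sv[j] / A[j];
    }
    return hval;
  };

  if (!propagate(ev_time, ev_amt, ev_obs, ev_n, ev_tau, ke0, nev, ka,
                 e2 - e1, true, Ac, S)) {
    out.ok = false; out.ofv = R_PosInf; return out;
  }
  h = fill(e1, e2, Ac, S);

  double g11 = 0, g12 = 0, g22 = 0, gr1 = 0, gr2 = 0;
  for (int it = 0; it < maxit; ++it) {
    g11 = g12 = g22 = gr1 = gr2 = 0.0;
    for (int j = 0; j < nobs; ++j) {
      const double G1 = -1.0 - g[j], G2 = g[j];
      g11 += G1 * G1; g12 += G1 * G2; g22 += G2 * G2;
      gr1 += G1 * r[j]; gr2 += G2 * r[j];
    }
    const double grad1 = f1 ? (-2.0 * gr1 / sigma2 + 2.0 * oi1 * e1) : 0.0;
    const double grad2 = f2 ? (-2.0 * gr2 / sigma2 + 2.0 * oi2 * e2) : 0.0;
    if (std::fabs(grad1) < gtol && std::fabs(grad2) < gtol) {
      out.converged = true; break;
    }
    const double H11 = 2.0 * g11 / sigma2 + 2.0 * oi1;
    const double H12 = 2.0 * g12 / sigma2;
    const double H22 = 2.0 * g22 / sigma2 + 2.0 * oi2;
    double d1 = 0.0, d2 = 0.0;
    if (f1 && f2) {
      const double det = H11 * H22 - H12 * H12;
      d1 = -(H22 * grad1 - H12 * grad2) / det;
      d2 = -(H11 * grad2 - H12 * grad1) / det;
    } else if (f1) d1 = -grad1 / H11;
    else if (f2) d2 = -grad2 / H22;
    else { out.converged = true; break; }
    double step = 1.0;
    int ls = 0;
    for (; ls < 30; ++ls) {
      const bool okp = propagate(ev_time, ev_amt, ev_obs, ev_n, ev_tau,
                                 ke0, nev, ka,
                                 (e2 + step * d2) - (e1 + step * d1), true,
                                 Ac_t, S_t);
      if (okp) {
        const double hnew = fill(e1 + step * d1, e2 + step * d2, Ac_t, S_t);
        if (hnew <= h + 1e-12) { h = hnew; break; }
      }
      step *= 0.5;
    }
    if (ls == 30) { // no descent found: restore state, accept current mode
      propagate(ev_time, ev_amt, ev_obs, ev_n, ev_tau, ke0, nev, ka,
                e2 - e1, true, Ac, S);
      h = fill(e1, e2, Ac, S);
      out.converged = true; break;
    }
    e1 += step * d1; e2 += step * d2;
  }

  // FOCE contribution with the linearization at the mode
  g11 = g12 = g22 = 0.0;
  for (int j = 0; j < nobs; ++j) {
    const double G1 = -1.0 - g[j], G2 = g[j];
    g11 += G1 * G1; g12 += G1 * G2; g22 += G2 * G2;
  }
  double logdet = 0.0;
  if (f1 && f2) {
    const double a11 = 1.0 + g11 / sigma2 * omega2[0];
    const double a12 = g12 / sigma2 * omega2[1];
    const double a21 = g12 / sigma2 * omega2[0];
    const double a22 = 1.0 + g22 / sigma2 * omega2[1];
    logdet = std::log(a11 * a22 - a12 * a21);
  } else if (f1) logdet = std::log(1.0 + g11 / sigma2 * omega2[0]);
  else if (f2) logdet = std::log(1.0 + g22 / sigma2 * omega2[1]);
  double ofv = oi1 * e1 * e1 + oi2 * e2 * e2 + logdet +
    nobs * std::log(2.0 * M_PI * sigma2);
  for (int j = 0; j < nobs; ++j) ofv += r[j] * r[j] / sigma2;

  out.ofv = ofv; out.eta1 = e1; out.eta2 = e2;
  out.lnc = lnc;
  out.G1.resize(nobs); out.G2.resize(nobs);
  for (int j = 0; j < nobs; ++j) { out.G1[j] = -1.0 - g[j]; out.G2[j] = g[j]; }
  return out;
}

// typical elimination rate per event: exp(log_thcl + Xb beta) / theta_v
std::vector<double> ke0_from(const NumericMatrix &Xb,
                             const NumericVector &beta,
                             double log_thcl, double theta_v) {
  const int nev = Xb.nrow(), k = beta.size();
  std::vector<double> ke0(nev);
  for (int i = 0; i < nev; ++i) {
    double lc = log_thcl;
    for (int j = 0; j < k; ++j) lc += Xb(i, j) * beta[j];
    ke0[i] = std::exp(lc) / theta_v;
  }
  return ke0;
}

} // namespace

// Conditional-mode (MAP) search and FOCE objective contribution for one
// subject.  omega2 entries equal to zero pin the corresponding eta at 0.
// [[Rcpp::export]]
List foce_subject_cpp(NumericVector ev_time, NumericVector ev_amt,
                      IntegerVector ev_obs, IntegerVector ev_n,
                      NumericVector ev_tau, NumericVector ke0,
                      double ka, double c0, NumericVector lobs,
                      double sigma2, NumericVector omega2,
                      NumericVector eta_start, int maxit = 60,
                      double gtol = 1e-7) {
  SubjectResult r = foce_one(ev_time.begin(), ev_amt.begin(),
                             ev_obs.begin(), ev_n.begin(), ev_tau.begin(),
                             ke0.begin(), ev_time.size(),
                             lobs.begin(), lobs.size(), ka, c0, sigma2,
                             omega2.begin(), eta_start.begin(), maxit, gtol);
  const int nobs = r.lnc.size();
  NumericMatrix G(nobs, 2);
  NumericVector lnc(nobs);
  for (int j = 0; j < nobs; ++j) {
    G(j, 0) = r.G1[j]; G(j, 1) = r.G2[j]; lnc[j] = r.lnc[j];
  }
  return List::create(_["ofv"] = r.ofv,
                      _["eta"] = NumericVector::create(r.eta1, r.eta2),
                      _["lnc"] = lnc, _["G"] = G,
                      _["converged"] = r.converged,
                      _["prior_only"] = r.prior_only, _["ok"] = r.ok);
}

namespace {

struct SubjData {
  std::vector<double> ev_time, ev_amt, ev_tau, lobs, Xb;
  std::vector<int> ev_obs, ev_n;
  int nev, nobs, k;
};

} // namespace

// Hoist the prepared subjects into plain C++ storage once per fit so the
// optimizer's objective evaluations do no R object access.
// [[Rcpp::export]]
SEXP foce_prepare_cpp(List subjects) {
  auto *dat = new std::vector<SubjData>(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) {
    List s = subjects[i];
    NumericVector ev_time = s["cev_time"], ev_amt = s["cev_amt"],
      ev_tau = s["cev_tau"], lobs = s["lobs"];
    IntegerVector ev_obs = s["cev_obs"], ev_n = s["cev_n"];
    NumericMatrix Xb = s["Xb"];
    SubjData &d = (*dat)[i];
    d.ev_time.assign(ev_time.begin(), ev_time.end());
    d.ev_amt.assign(ev_amt.begin(), ev_amt.end());
    d.ev_tau.assign(ev_tau.begin(), ev_tau.end());
    d.lobs.assign(lobs.begin(), lobs.end());
    d.ev_obs.assign(ev_obs.begin(), ev_obs.end());
    d.ev_n.assign(ev_n.begin(), ev_n.end());
    d.Xb.assign(Xb.begin(), Xb.end());
    d.nev = ev_time.size(); d.nobs = lobs.size(); d.k = Xb.ncol();
  }
  XPtr<std::vector<SubjData> > ptr(dat, true);
  return ptr;
}

// Cohort objective against a prepared pointer; returns the summed OFV and
// per-subject contributions (objective evaluations allocate nothing in R).
// [[Rcpp::export]]
List foce_cohort_ptr_cpp(SEXP prep_ptr, NumericVector beta, double log_thcl,
                         double theta_v, double ka, double sigma2,
                         NumericVector omega2, int maxit = 60,
                         double gtol = 1e-7) {
  XPtr<std::vector<SubjData> > ptr(prep_ptr);
  const std::vector<SubjData> &dat = *ptr;
  const int n = dat.size();
  const double c0 = std::log(1000.0 / theta_v);
  NumericVector contrib(n);
  NumericMatrix eta(n, 2);
  double tot = 0.0;
  bool all_ok = true;
  int bad = -1;
  std::vector<double> ke0;
  for (int i = 0; i < n; ++i) {
    const SubjData &d = dat[i];
    ke0.resize(d.nev);
    for (int e = 0; e < d.nev; ++e) {
      double lc = log_thcl;
      for (int j = 0; j < d.k; ++j) lc += d.Xb[e + j * d.nev] * beta[j];
      ke0[e] = std::exp(lc) / theta_v;
    }
    double es[2] = { 0.0, 0.0 };
    SubjectResult r = foce_one(d.ev_time.data(), d.ev_amt.data(),
                               d.ev_obs.data(), d.ev_n.data(),
                               d.ev_tau.data(), ke0.data(), d.nev,
                               d.lobs.data(), d.nobs, ka, c0, sigma2,
                               omega2.begin(), es, maxit, gtol);
    if (!r.ok || !std::isfinite(r.ofv)) { all_ok = false; bad = i; break; }
    contrib[i] = r.ofv;
    eta(i, 0) = r.eta1; eta(i, 1) = r.eta2;
    tot += r.ofv;
  }
  return List::create(_["ofv"] = all_ok ? tot : R_PosInf,
                      _["contrib"] = contrib, _["eta"] = eta,
                      _["ok"] = all_ok, _["bad"] = bad + 1);
}
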