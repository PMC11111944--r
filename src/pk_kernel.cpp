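#include <Rcpp.h>
using namespace Rcpp;

// One-compartment, first-order absorption/elimination state propagation
// across a time-sorted event schedule with piecewise-constant elimination
// rate (covariates may change CL between records).  ev_amt > 0 deposits
// drug into the depot at the event instant -- after any observation that
// shares the same timestamp, so a trough drawn "just before the morning
// dose" can sit at the dose time.  Rows with ev_obs == 1 report the
// central-compartment amount and, when grad is true, its sensitivity
// dAc/du under the scaling ke -> ke * exp(u) applied to every segment
// (u is the log-elimination perturbation the conditional-mode search
// moves along).
// [[Rcpp::export]]
NumericMatrix pk_propagate_cpp(NumericVector ev_time, NumericVector ev_amt,
                               IntegerVector ev_obs, NumericVector ke_ev,
                               double ka, bool grad) {
  const int n = ev_time.size();
  int nobs = 0;
  for (int i = 0; i < n; ++i) if (ev_obs[i]) ++nobs;
  NumericMatrix out(nobs, 2);
  double Ag = 0.0, Ac = 0.0, S = 0.0;
  double tcur = (n > 0) ? ev_time[0] : 0.0;
  int io = 0;
  for (int i = 0; i < n; ++i) {
    const double dt = ev_time[i] - tcur;
    const double ke = ke_ev[i];
    if (dt > 0.0) {
      const double Ea = std::exp(-ka * dt);
      double Ee, B, dB;
      if (std::fabs(ka - ke) > 1e-8 * ka) {
        Ee = std::exp(-ke * dt);
        const double f = (Ee - Ea) / (ka - ke);
        B = ka * f;
        // dB/du = ke * dB/dke
        dB = ke * (ka * f / (ka - ke) - ka / (ka - ke) * dt * Ee);
      } else {
        // ke -> ka limit of ka*(e^{-ke dt} - e^{-ka dt})/(ka - ke)
        Ee = Ea;
        B = ka * dt * Ea;
        dB = ke * (-0.5 * ka * dt * dt * Ea);
      }
      const double Ac_new = Ac * Ee + Ag * B;
      if (grad) S = S * Ee + Ac * (-dt * ke * Ee) + Ag * dB;
      Ac = Ac_new;
      Ag *= Ea;
      tcur = ev_time[i];
    }
    if (ev_obs[i]) { out(io, 0) = Ac; out(io, 1) = S; ++io; }
    if (ev_amt[i] > 0.0) Ag += ev_amt[i];
  }
  return out;
}
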