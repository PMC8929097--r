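#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integrator for the lumen transit/dissolution/absorption
// system coupled to a one-compartment central amount.
//
// State layout (n = number of GI compartments):
//   y[0..n)      undissolved mass per compartment, mg
//   y[n..2n)     dissolved mass per compartment, mg
//   y[2n..3n)    cumulative absorbed mass per compartment, mg
//   y[3n]        cumulative mass excreted from the last compartment, mg
//   y[3n+1]      central-compartment amount, mg
//
// All rate constants are 1/h; kd_coef is mL/(mg h) so that
// dissolution = kd_coef * undissolved * (Cs - C) is mg/h.
// The stomach luminal volume is time-varying: each oral dose adds its dose
// volume, which empties first-order with the gastric transit rate.

namespace {

struct AcatPars {
  int n;
  const double *kt;      // transit rate 1/h
  const double *vol;     // resting volume mL
  const double *ka;      // absorption rate 1/h (includes ASF)
  double kd_coef, kdiss_max, cs, inv_tau_p, kel, egut, ehep;
  const double *dose_t;  // dose times, h (sorted)
  const double *dose_v;  // dose volumes, mL
  int n_dose;
};

inline double stomach_volume(const AcatPars &p, double t) {
  double v = p.vol[0];
  for (int d = 0; d < p.n_dose; ++d) {
    if (t >= p.dose_t[d])
      v += p.dose_v[d] * std::exp(-p.kt[0] * (t - p.dose_t[d]));
  }
  return v;
}

void rhs(const AcatPars &p, double t, const std::vector<double> &y,
         std::vector<double> &dy) {
  const int n = p.n;
  double v0 = stomach_volume(p, t);
  double portal = 0.0;
  for (int i = 0; i < n; ++i) {
    double U = y[i], S = y[n + i];
    double V = (i == 0) ? v0 : p.vol[i];
    double C = S / V;
    // dissolution rate constant capped at kdiss_max (numerically
    // "instantaneous" dissolution; timescale << any transit process)
    double kdis = (C < p.cs) ? p.kd_coef * (p.cs - C) : 0.0;
    if (kdis > p.kdiss_max) kdis = p.kdiss_max;
    double diss = kdis * U;
    double prec = (C > p.cs) ? (C - p.cs) * V * p.inv_tau_p : 0.0;
    double in_U = (i > 0) ? p.kt[i - 1] * y[i - 1] : 0.0;
    double in_S = (i > 0) ? p.kt[i - 1] * y[n + i - 1] : 0.0;
    double abs_i = p.ka[i] * S;
    dy[i] = -diss + prec - p.kt[i] * U + in_U;
    dy[n + i] = diss - prec - p.kt[i] * S - abs_i + in_S;
    dy[2 * n + i] = abs_i;
    portal += abs_i;
  }
  dy[3 * n] = p.kt[n - 1] * (y[n - 1] + y[2 * n - 1]);
  dy[3 * n + 1] =
      (1.0 - p.ehep) * (1.0 - p.egut) * portal - p.kel * y[3 * n + 1];
}

}  // namespace

// [[Rcpp::export]]
List cpp_acat_simulate(NumericVector transit_k, NumericVector volume,
                       NumericVector ka, double kd_coef, double kdiss_max,
                       double cs, double tau_precip, double kel, double egut,
                       double ehep, NumericVector dose_steps,
                       NumericVector dose_amounts, NumericVector dose_volumes,
                       bool predissolved, double dt_out, int n_out,
                       int n_sub) {
  const int n = transit_k.size();
  AcatPars p;
  p.n = n;
  p.kt = transit_k.begin();
  p.vol = volume.begin();
  p.ka = ka.begin();
  p.kd_coef = kd_coef;
  p.kdiss_max = kdiss_max;
  p.cs = cs;
  p.inv_tau_p = 1.0 / tau_precip;
  p.kel = kel;
  p.egut = egut;
  p.ehep = ehep;
  std::vector<double> dose_t(dose_steps.size());
  for (int d = 0; d < dose_steps.size(); ++d)
    dose_t[d] = dose_steps[d] * dt_out;
  p.dose_t = dose_t.data();
  p.dose_v = dose_volumes.begin();
  p.n_dose = dose_steps.size();

  const int ns = 3 * n + 2;
  std::vector<double> y(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  NumericMatrix out(n_out + 1, ns);
  NumericVector portal_out(n_out + 1);

  const double h = dt_out / n_sub;
  int next_dose = 0;
  for (int j = 0; j <= n_out; ++j) {
    double t = j * dt_out;
    // apply any dose scheduled at this grid point
    while (next_dose < p.n_dose && dose_steps[next_dose] == j) {
      if (predissolved)
        y[n] += dose_amounts[next_dose];
      else
        y[0] += dose_amounts[next_dose];
      ++next_dose;
    }
    for (int s = 0; s < ns; ++s) out(j, s) = y[s];
    {  // portal flux (into the portal vein) at the output time
      double fl = 0.0;
      for (int i = 0; i < n; ++i) fl += p.ka[i] * y[n + i];
      portal_out[j] = (1.0 - p.egut) * fl;
    }
    if (j == n_out) break;
    for (int s = 0; s < n_sub; ++s) {
      double ts = t + s * h;
      rhs(p, ts, y, k1);
      for (int q = 0; q < ns; ++q) tmp[q] = y[q] + 0.5 * h * k1[q];
      rhs(p, ts + 0.5 * h, tmp, k2);
      for (int q = 0; q < ns; ++q) tmp[q] = y[q] + 0.5 * h * k2[q];
      rhs(p, ts + 0.5 * h, tmp, k3);
      for (int q = 0; q < ns; ++q) tmp[q] = y[q] + h * k3[q];
      rhs(p, ts + h, tmp, k4);
      for (int q = 0; q < ns; ++q) {
        y[q] += h / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
        if (y[q] < 0.0 && y[q] > -1e-12) y[q] = 0.0;
      }
    }
  }
  return List::create(_["states"] = out, _["portal"] = portal_out);
}
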