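// Single-compartment conductance-based neuron: transient Na (m^3 h),
// persistent Na (single activation gate, rates scaled by nap_rate_factor,
// no inactivation gate), delayed-rectifier K (n^4), slow non-inactivating K
// (M-type gate p), and leak. Traub-type rate functions with a VT shift.
// Integration: forward Euler for V, exponential Euler for every gate (exact
// for frozen V, which keeps the 1000x-fast persistent-Na gate stable).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (exp(x / y) - 1), guarded at the removable singularity
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

struct Rates {
  double am, bm, ah, bh, an, bn, pinf, ptau;
};

static inline Rates rates(double v, double vt, double tau_max,
                          double h_mult) {
  Rates r;
  double u = v - vt;
  r.am = 0.32 * vtrap(13.0 - u, 4.0);
  r.bm = 0.28 * vtrap(u - 40.0, 5.0);
  r.ah = 0.128 * std::exp(-(u - 17.0) / 18.0);
  r.bh = h_mult * 4.0 / (1.0 + std::exp(-(u - 40.0) / 5.0));
  r.an = 0.032 * vtrap(15.0 - u, 5.0);
  r.bn = 0.5 * std::exp(-(u - 10.0) / 40.0);
  r.pinf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.ptau = tau_max / (3.3 * std::exp((v + 35.0) / 20.0) +
                      std::exp(-(v + 35.0) / 20.0));
  return r;
}

static inline double expo_step(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

struct Params {
  double cm, g_na, g_nap, g_kd, g_km, g_leak;
  double e_na, e_k, e_leak, vt, tau_max, h_mult, nap_fac;
};

static Params unpack(const NumericVector& p) {
  Params q;
  q.cm = p["cm"];       q.g_na = p["g_na"];   q.g_nap = p["g_nap"];
  q.g_kd = p["g_kd"];   q.g_km = p["g_km"];   q.g_leak = p["g_leak"];
  q.e_na = p["e_na"];   q.e_k = p["e_k"];     q.e_leak = p["e_leak"];
  q.vt = p["vt"];       q.tau_max = p["tau_max"];
  q.h_mult = p["h_mult"]; q.nap_fac = p["nap_fac"];
  return q;
}

// [[Rcpp::export(name = ".hh_run")]]
List hh_run(NumericVector params, NumericVector stim_density, double dt,
            int record_every, double settle_ms) {
  Params q = unpack(params);
  const double v_lo = q.e_k - 40.0, v_hi = q.e_na + 40.0;

  double v = q.e_leak;
  Rates r = rates(v, q.vt, q.tau_max, q.h_mult);
  double m = r.am / (r.am + r.bm);
  double h = r.ah / (r.ah + r.bh);
  double n = r.an / (r.an + r.bn);
  double pg = r.pinf;
  double mp = r.am / (r.am + r.bm); // same voltage dependence, faster rates

  double gmin = 1.0, gmax = 0.0;
  int n_settle = (int)std::ceil(settle_ms / dt);
  int n_stim = stim_density.size();
  int n_total = n_settle + n_stim;

  int n_rec = (n_stim + record_every - 1) / record_every + 1;
  NumericVector rec_t(n_rec), rec_v(n_rec);
  std::vector<double> spikes;
  double last_spike = -1e9;
  int irec = 0;

  for (int i = 0; i < n_total; ++i) {
    bool in_stim = i >= n_settle;
    double t = in_stim ? (i - n_settle) * dt : 0.0;
    double istim = in_stim ? stim_density[i - n_settle] : 0.0;

    if (in_stim && (i - n_settle) % record_every == 0 && irec < n_rec) {
      rec_t[irec] = t; rec_v[irec] = v; ++irec;
    }

    r = rates(v, q.vt, q.tau_max, q.h_mult);
    double ina = q.g_na * m * m * m * h * (v - q.e_na);
    double inap = q.g_nap * mp * (v - q.e_na);
    double ik = q.g_kd * n * n * n * n * (v - q.e_k);
    double ikm = q.g_km * pg * (v - q.e_k);
    double il = q.g_leak * (v - q.e_leak);

    double v_new = v + dt / q.cm * (istim - ina - inap - ik - ikm - il);

    m = expo_step(m, r.am / (r.am + r.bm), 1.0 / (r.am + r.bm), dt);
    h = expo_step(h, r.ah / (r.ah + r.bh), 1.0 / (r.ah + r.bh), dt);
    n = expo_step(n, r.an / (r.an + r.bn), 1.0 / (r.an + r.bn), dt);
    pg = expo_step(pg, r.pinf, r.ptau, dt);
    mp = expo_step(mp, r.am / (r.am + r.bm),
                   1.0 / (q.nap_fac * (r.am + r.bm)), dt);

    for (double g : {m, h, n, pg, mp}) {
      if (g < gmin) gmin = g;
      if (g > gmax) gmax = g;
    }

    if (in_stim && v < 0.0 && v_new >= 0.0 && t - last_spike >= 1.0) {
      spikes.push_back(t);
      last_spike = t;
    }

    if (!std::isfinite(v_new) || v_new < v_lo || v_new > v_hi)
      stop("integration-failure error at t = %f ms (v = %f mV)", t, v_new);
    v = v_new;
  }
  // record the final sample
  if (irec < n_rec) {
    rec_t[irec] = n_stim * dt; rec_v[irec] = v; ++irec;
  }
  if (irec < n_rec) {
    rec_t = rec_t[Range(0, irec - 1)];
    rec_v = rec_v[Range(0, irec - 1)];
  }

  return List::create(_["time"] = rec_t, _["v"] = rec_v,
                      _["spike_times"] = wrap(spikes),
                      _["gating_range"] = NumericVector::create(gmin, gmax),
                      _["v_final"] = v);
}

// Voltage clamp on the model's sodium currents: gating ODEs driven by the
// commanded voltage; returns the total Na current (fast + persistent,
// uA/cm2) at every step.
// [[Rcpp::export(name = ".hh_vclamp")]]
NumericVector hh_vclamp(NumericVector params, NumericVector v_command,
                        double dt) {
  Params q = unpack(params);
  int n = v_command.size();
  if (n < 2) stop("v_command must have >= 2 samples");

  double v0 = v_command[0];
  Rates r = rates(v0, q.vt, q.tau_max, q.h_mult);
  double m = r.am / (r.am + r.bm);
  double h = r.ah / (r.ah + r.bh);
  double mp = m;

  NumericVector ina(n);
  for (int i = 0; i < n; ++i) {
    double v = v_command[i];
    r = rates(v, q.vt, q.tau_max, q.h_mult);
    ina[i] = q.g_na * m * m * m * h * (v - q.e_na) +
             q.g_nap * mp * (v - q.e_na);
    m = expo_step(m, r.am / (r.am + r.bm), 1.0 / (r.am + r.bm), dt);
    h = expo_step(h, r.ah / (r.ah + r.bh), 1.0 / (r.ah + r.bh), dt);
    mp = expo_step(mp, r.am / (r.am + r.bm),
                   1.0 / (q.nap_fac * (r.am + r.bm)), dt);
  }
  return ina;
}
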