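// Fixed-step integration of the stellate/interneuron conductance-based
// network. State layout: per-cell blocks (stellate: v,m,h,n,ms,mhf,mhs;
// interneuron: v,m,h,n) followed by one synaptic gate per cell (the cell's
// outgoing gate; excitatory for stellate cells, inhibitory for interneurons).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double xexp(double x) { return std::exp(x); }

// x / (e^x - 1), continuous at x = 0 (series branch near the singularity)
static inline double vtrap(double x) {
  if (std::fabs(x) < 1e-7) return 1.0 - x / 2.0 + x * x / 12.0;
  return x / (std::expm1(x));
}

struct StelPar {
  double c_m, g_na, g_k, g_nap, g_h, g_leak;
  double e_na, e_k, e_h, e_leak, tau_ms, fh_fast, fh_slow;
};
struct IntPar {
  double c_m, g_na, g_k, g_leak, e_na, e_k, e_leak, phi;
};

// stellate transient-Na / K rate functions
static inline void stel_rates(double v, double& am, double& bm, double& ah,
                              double& bh, double& an, double& bn) {
  am = vtrap(-0.1 * (v + 23.0));
  bm = 4.0 * xexp(-(v + 48.0) / 18.0);
  ah = 0.07 * xexp(-(v + 37.0) / 20.0);
  bh = 1.0 / (xexp(-0.1 * (v + 7.0)) + 1.0);
  an = 0.1 * vtrap(-0.1 * (v + 27.0));
  bn = 0.125 * xexp(-(v + 37.0) / 80.0);
}
static inline void stel_slow(double v, double& ms_inf, double& mhf_inf,
                             double& tau_mhf, double& mhs_inf, double& tau_mhs) {
  ms_inf = 1.0 / (1.0 + xexp(-(v + 38.0) / 6.5));
  mhf_inf = 1.0 / (1.0 + xexp((v + 79.2) / 9.78));
  tau_mhf = 0.51 / (xexp((v - 1.7) / 10.0) + xexp(-(v + 340.0) / 52.0)) + 1.0;
  mhs_inf = std::pow(1.0 + xexp((v + 2.83) / 15.9), -58.0);
  tau_mhs = 5.6 / (xexp((v - 1.7) / 14.0) + xexp(-(v + 260.0) / 43.0)) + 1.0;
}
static inline void int_rates(double v, double& am, double& bm, double& ah,
                             double& bh, double& an, double& bn) {
  am = vtrap(-(v + 35.0) / 10.0);
  bm = 4.0 * xexp(-(v + 60.0) / 18.0);
  ah = 0.07 * xexp(-(v + 58.0) / 20.0);
  bh = 1.0 / (xexp(-0.1 * (v + 28.0)) + 1.0);
  an = 0.1 * vtrap(-0.1 * (v + 34.0));
  bn = 0.125 * xexp(-(v + 44.0) / 80.0);
}

static inline double presyn_act(double v) {
  return (1.0 + std::tanh(v / 4.0)) / 2.0;
}

struct PulseCell {
  std::vector<double> onsets;  // sorted
  double p_low, p_high, tau_r, tau_f, width, p_te;
  double value(double t) const {
    if (onsets.empty() || t < onsets[0]) return onsets.empty() ? 0.0 : p_low;
    // last onset <= t
    size_t k = std::upper_bound(onsets.begin(), onsets.end(), t) - onsets.begin() - 1;
    double ts = onsets[k];
    if (t < ts + width)
      return p_high + (p_low - p_high) * xexp(-(t - ts) / tau_r);
    return p_low + (p_te - p_low) * xexp(-(t - (ts + width)) / tau_f);
  }
};

struct Theta {
  bool on = false;
  double A = 0, phase0 = 0, v_th = -80, freq = 8;
  bool sweep = false;
  double f_mid = 0, f_half = 0, period = 1;
  double phase(double t) const {
    if (!sweep) return phase0 + 2.0 * M_PI * freq * t / 1000.0;
    double two_pi = 2.0 * M_PI;
    return phase0 + (two_pi / 1000.0) *
      (f_mid * t + f_half * (period / two_pi) * (1.0 - std::cos(two_pi * t / period)));
  }
  double current(double t, double v) const {
    if (!on) return 0.0;
    return A * std::sin(phase(t)) * (v - v_th);
  }
};

struct Model {
  int nc;
  std::vector<int> type;          // 0 stellate, 1 interneuron
  std::vector<int> off;           // state offset per cell
  int s_off;                      // offset of synaptic gates
  int nstate;
  std::vector<double> drive;
  StelPar sp; IntPar ip;
  double exc_erev, exc_a, exc_b, inh_erev, inh_a, inh_b;
  std::vector<int> e_pre, e_post; std::vector<double> e_w;
  std::vector<PulseCell> pulse;   // size nc (empty onsets = no pulse)
  std::vector<bool> has_pulse;
  Theta theta;
  std::vector<bool> theta_mask;   // interneurons
  double noise_g, noise_erev;

  // u: per-cell noise draw in [-1,1], held for the step
  void rhs(double t, const std::vector<double>& y, std::vector<double>& dy,
           const std::vector<double>& u) const {
    // synaptic conductance accumulators
    std::vector<double> g_exc(nc, 0.0), g_inh(nc, 0.0);
    for (size_t e = 0; e < e_pre.size(); ++e) {
      double s = y[s_off + e_pre[e]];
      if (type[e_pre[e]] == 0) g_exc[e_post[e]] += e_w[e] * s;
      else                     g_inh[e_post[e]] += e_w[e] * s;
    }
    for (int i = 0; i < nc; ++i) {
      int o = off[i];
      double v = y[o];
      double i_syn = g_exc[i] * (v - exc_erev) + g_inh[i] * (v - inh_erev);
      double i_noise = noise_g * u[i] * (v - noise_erev);
      if (type[i] == 0) {
        double m = y[o + 1], h = y[o + 2], n = y[o + 3];
        double ms = y[o + 4], mhf = y[o + 5], mhs = y[o + 6];
        double am, bm, ah, bh, an, bn, ms_inf, mhf_inf, tau_mhf, mhs_inf, tau_mhs;
        stel_rates(v, am, bm, ah, bh, an, bn);
        stel_slow(v, ms_inf, mhf_inf, tau_mhf, mhs_inf, tau_mhs);
        double i_na = sp.g_na * m * m * m * h * (v - sp.e_na);
        double i_k = sp.g_k * n * n * n * n * (v - sp.e_k);
        double i_l = sp.g_leak * (v - sp.e_leak);
        double i_h = sp.g_h * (sp.fh_fast * mhf + sp.fh_slow * mhs) * (v - sp.e_h);
        double i_nap = sp.g_nap * ms * (v - sp.e_na);
        dy[o] = (drive[i] - i_na - i_k - i_l - i_h - i_nap - i_syn - i_noise) / sp.c_m;
        dy[o + 1] = am * (1.0 - m) - bm * m;
        dy[o + 2] = ah * (1.0 - h) - bh * h;
        dy[o + 3] = an * (1.0 - n) - bn * n;
        dy[o + 4] = (ms_inf - ms) / sp.tau_ms;
        dy[o + 5] = (mhf_inf - mhf) / tau_mhf;
        dy[o + 6] = (mhs_inf - mhs) / tau_mhs;
      } else {
        // fast-spiking interneuron: Na activation m is instantaneous
        double h = y[o + 1], n = y[o + 2];
        double am, bm, ah, bh, an, bn;
        int_rates(v, am, bm, ah, bh, an, bn);
        double m = am / (am + bm);
        double i_na = ip.g_na * m * m * m * h * (v - ip.e_na);
        double i_k = ip.g_k * n * n * n * n * (v - ip.e_k);
        double i_l = ip.g_leak * (v - ip.e_leak);
        double i_pulse = has_pulse[i] ? pulse[i].value(t) : 0.0;
        double i_theta = theta_mask[i] ? theta.current(t, v) : 0.0;
        dy[o] = (drive[i] + i_pulse - i_na - i_k - i_l - i_syn - i_noise - i_theta) / ip.c_m;
        dy[o + 1] = ip.phi * (ah * (1.0 - h) - bh * h);
        dy[o + 2] = ip.phi * (an * (1.0 - n) - bn * n);
      }
      // outgoing synaptic gate
      double s = y[s_off + i];
      double F = presyn_act(v);
      if (type[i] == 0) dy[s_off + i] = F * exc_a * (1.0 - s) - exc_b * s;
      else              dy[s_off + i] = F * inh_a * (1.0 - s) - inh_b * s;
    }
  }
};

static double getd(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

// [[Rcpp::export]]
List run_sim_cpp(IntegerVector cell_type, NumericVector drive,
                 List stellate_par, List inter_par,
                 NumericVector syn_exc, NumericVector syn_inh,
                 IntegerVector edge_pre, IntegerVector edge_post,
                 NumericVector edge_w,
                 List pulse_spec, List theta_spec,
                 double noise_g, double noise_erev,
                 double dt, double duration, int method,
                 double seed,
                 double init_v_lo, double init_v_hi, NumericVector init_v_fixed,
                 IntegerVector record_cells, double record_every,
                 double spike_thresh, double refractory) {
  Model M;
  M.nc = cell_type.size();
  M.type.assign(cell_type.begin(), cell_type.end());
  M.drive.assign(drive.begin(), drive.end());
  M.off.resize(M.nc);
  int pos = 0;
  for (int i = 0; i < M.nc; ++i) {
    M.off[i] = pos;
    pos += (M.type[i] == 0) ? 7 : 3;
  }
  M.s_off = pos;
  M.nstate = pos + M.nc;

  M.sp = { getd(stellate_par, "c_m"), getd(stellate_par, "g_na"),
           getd(stellate_par, "g_k"), getd(stellate_par, "g_nap"),
           getd(stellate_par, "g_h"), getd(stellate_par, "g_leak"),
           getd(stellate_par, "e_na"), getd(stellate_par, "e_k"),
           getd(stellate_par, "e_h"), getd(stellate_par, "e_leak"),
           getd(stellate_par, "tau_ms"), getd(stellate_par, "h_frac_fast"),
           getd(stellate_par, "h_frac_slow") };
  M.ip = { getd(inter_par, "c_m"), getd(inter_par, "g_na"),
           getd(inter_par, "g_k"), getd(inter_par, "g_leak"),
           getd(inter_par, "e_na"), getd(inter_par, "e_k"),
           getd(inter_par, "e_leak"), getd(inter_par, "phi") };
  M.exc_erev = syn_exc[0]; M.exc_a = syn_exc[1]; M.exc_b = syn_exc[2];
  M.inh_erev = syn_inh[0]; M.inh_a = syn_inh[1]; M.inh_b = syn_inh[2];

  int ne = edge_pre.size();
  M.e_pre.resize(ne); M.e_post.resize(ne); M.e_w.resize(ne);
  for (int e = 0; e < ne; ++e) {
    M.e_pre[e] = edge_pre[e] - 1;
    M.e_post[e] = edge_post[e] - 1;
    M.e_w[e] = edge_w[e];
  }

  M.pulse.resize(M.nc);
  M.has_pulse.assign(M.nc, false);
  if (pulse_spec.size() > 0) {
    IntegerVector pc = pulse_spec["cells"];
    List onsets = pulse_spec["onsets"];
    NumericVector pl = pulse_spec["p_low"], ph = pulse_spec["p_high"];
    NumericVector tr = pulse_spec["tau_r"], tf = pulse_spec["tau_f"];
    NumericVector wd = pulse_spec["width"];
    for (int j = 0; j < pc.size(); ++j) {
      int c = pc[j] - 1;
      PulseCell& P = M.pulse[c];
      NumericVector on = onsets[j];
      P.onsets.assign(on.begin(), on.end());
      std::sort(P.onsets.begin(), P.onsets.end());
      P.p_low = pl[j]; P.p_high = ph[j]; P.tau_r = tr[j]; P.tau_f = tf[j];
      P.width = wd[j];
      P.p_te = P.p_high + (P.p_low - P.p_high) * xexp(-P.width / P.tau_r);
      M.has_pulse[c] = true;
    }
  }

  M.theta_mask.assign(M.nc, false);
  for (int i = 0; i < M.nc; ++i)
    if (M.type[i] == 1) M.theta_mask[i] = true;
  if (theta_spec.size() > 0) {
    M.theta.on = true;
    M.theta.A = getd(theta_spec, "amplitude");
    M.theta.phase0 = getd(theta_spec, "phase");
    M.theta.v_th = getd(theta_spec, "v_th");
    if (theta_spec.containsElementNamed("sweep") &&
        !Rf_isNull(theta_spec["sweep"])) {
      List sw = theta_spec["sweep"];
      M.theta.sweep = true;
      M.theta.f_mid = (getd(sw, "f_min") + getd(sw, "f_max")) / 2.0;
      M.theta.f_half = (getd(sw, "f_max") - getd(sw, "f_min")) / 2.0;
      M.theta.period = getd(sw, "period");
    } else {
      M.theta.freq = getd(theta_spec, "freq");
    }
  }
  M.noise_g = noise_g; M.noise_erev = noise_erev;

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  // initial conditions: v per cell, gates at steady state for that v
  std::vector<double> y(M.nstate, 0.0);
  for (int i = 0; i < M.nc; ++i) {
    double v;
    if (init_v_fixed.size() == M.nc) v = init_v_fixed[i];
    else v = init_v_lo + (init_v_hi - init_v_lo) * unif01(rng);
    int o = M.off[i];
    y[o] = v;
    if (M.type[i] == 0) {
      double am, bm, ah, bh, an, bn, ms_inf, mhf_inf, tmf, mhs_inf, tms;
      stel_rates(v, am, bm, ah, bh, an, bn);
      stel_slow(v, ms_inf, mhf_inf, tmf, mhs_inf, tms);
      y[o + 1] = am / (am + bm);
      y[o + 2] = ah / (ah + bh);
      y[o + 3] = an / (an + bn);
      y[o + 4] = ms_inf; y[o + 5] = mhf_inf; y[o + 6] = mhs_inf;
    } else {
      double am, bm, ah, bh, an, bn;
      int_rates(v, am, bm, ah, bh, an, bn);
      y[o + 1] = ah / (ah + bh);
      y[o + 2] = an / (an + bn);
    }
    y[M.s_off + i] = 0.0;
  }

  long nstep = (long)std::llround(duration / dt);
  int stride = record_every > 0 ? std::max(1, (int)std::lround(record_every / dt)) : 0;
  int nrec = record_cells.size();
  std::vector<double> rec_t;
  std::vector<std::vector<double>> rec_v(nrec);
  if (stride > 0 && nrec > 0) {
    long cap = nstep / stride + 2;
    rec_t.reserve(cap);
    for (int j = 0; j < nrec; ++j) rec_v[j].reserve(cap);
  }

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  std::vector<double> last_spike(M.nc, -1e9), prev_v(M.nc);
  for (int i = 0; i < M.nc; ++i) prev_v[i] = y[M.off[i]];

  std::vector<double> u(M.nc, 0.0), dy(M.nstate), yk(M.nstate);
  std::vector<double> k1(M.nstate), k2(M.nstate), k3(M.nstate), k4(M.nstate);
  long clamp_count = 0;
  bool diverged = false;
  double t_div = NA_REAL;

  auto record = [&](double t) {
    if (stride > 0 && nrec > 0) {
      rec_t.push_back(t);
      for (int j = 0; j < nrec; ++j)
        rec_v[j].push_back(y[M.off[record_cells[j] - 1]]);
    }
  };
  record(0.0);

  for (long st = 0; st < nstep && !diverged; ++st) {
    double t = st * dt;
    if (M.noise_g > 0) {
      for (int i = 0; i < M.nc; ++i) u[i] = 2.0 * unif01(rng) - 1.0;
    }
    if (method == 0) {
      M.rhs(t, y, dy, u);
      for (int s = 0; s < M.nstate; ++s) y[s] += dt * dy[s];
    } else {
      M.rhs(t, y, k1, u);
      for (int s = 0; s < M.nstate; ++s) yk[s] = y[s] + 0.5 * dt * k1[s];
      M.rhs(t + 0.5 * dt, yk, k2, u);
      for (int s = 0; s < M.nstate; ++s) yk[s] = y[s] + 0.5 * dt * k2[s];
      M.rhs(t + 0.5 * dt, yk, k3, u);
      for (int s = 0; s < M.nstate; ++s) yk[s] = y[s] + dt * k3[s];
      M.rhs(t + dt, yk, k4, u);
      for (int s = 0; s < M.nstate; ++s)
        y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);
    }
    // clamp gating and synaptic variables to [0,1]
    for (int i = 0; i < M.nc; ++i) {
      int o = M.off[i], ng = (M.type[i] == 0) ? 6 : 2;
      for (int g = 1; g <= ng; ++g) {
        if (y[o + g] < 0.0) { y[o + g] = 0.0; ++clamp_count; }
        else if (y[o + g] > 1.0) { y[o + g] = 1.0; ++clamp_count; }
      }
      int so = M.s_off + i;
      if (y[so] < 0.0) { y[so] = 0.0; ++clamp_count; }
      else if (y[so] > 1.0) { y[so] = 1.0; ++clamp_count; }
    }
    double t_next = (st + 1) * dt;
    for (int i = 0; i < M.nc; ++i) {
      double v = y[M.off[i]];
      if (!std::isfinite(v) || std::fabs(v) > 200.0) {
        diverged = true; t_div = t_next; break;
      }
      if (prev_v[i] < spike_thresh && v >= spike_thresh &&
          (t_next - last_spike[i]) > refractory) {
        double tc = t + dt * (spike_thresh - prev_v[i]) / (v - prev_v[i]);
        spike_cell.push_back(i + 1);
        spike_time.push_back(tc);
        last_spike[i] = tc;
      }
      prev_v[i] = v;
    }
    if (!diverged && stride > 0 && ((st + 1) % stride == 0)) record(t_next);
  }

  NumericVector fin_v(M.nc);
  for (int i = 0; i < M.nc; ++i) fin_v[i] = y[M.off[i]];

  NumericMatrix tv(rec_t.size(), nrec);
  for (int j = 0; j < nrec; ++j)
    for (size_t r = 0; r < rec_t.size(); ++r) tv(r, j) = rec_v[j][r];

  return List::create(
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_time),
    _["clamp_count"] = (double)clamp_count,
    _["diverged"] = diverged,
    _["t_diverged"] = t_div,
    _["trace_t"] = wrap(rec_t),
    _["trace_v"] = tv,
    _["final_v"] = fin_v);
}

// Uniform(-1, 1) stream from the engine's generator family; used to verify
// the noise distribution.
// [[Rcpp::export]]
NumericVector unif_sym_cpp(int n, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = 2.0 * unif01(rng) - 1.0;
  return out;
}
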