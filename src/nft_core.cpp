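#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

// Deterministic Gaussian stream: mt19937_64 + Box-Muller. Kept independent of
// R's RNG so that paired runs (SHAM vs STIM, same seed) consume bit-identical
// noise regardless of what the protocol draws on the R side.
struct GaussStream {
  std::mt19937_64 gen;
  double spare;
  bool has_spare;
  explicit GaussStream(uint64_t seed) : gen(seed), spare(0.0), has_spare(false) {}
  double unif() {
    // in (0, 1]
    return (static_cast<double>(gen() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// Direct-form-II-transposed IIR of arbitrary order (a[0] assumed 1).
struct Iir {
  std::vector<double> b, a, s;
  void init(const NumericVector& bb, const NumericVector& aa) {
    b.assign(bb.begin(), bb.end());
    a.assign(aa.begin(), aa.end());
    size_t n = std::max(b.size(), a.size());
    b.resize(n, 0.0); a.resize(n, 0.0);
    s.assign(n - 1, 0.0);
  }
  double step(double x) {
    double y = b[0] * x + s[0];
    size_t n = s.size();
    for (size_t i = 0; i < n - 1; ++i) s[i] = b[i + 1] * x + s[i + 1] - a[i + 1] * y;
    s[n - 1] = b[n] * x - a[n] * y;
    return y;
  }
};

// Online phase estimator + hysteresis trigger: inverse-notch resonator,
// peak-hold envelope with exponential decay, quadrature filter, elliptical
// phase recovery from the designed quadrature response (gain g, shift psi).
struct PhaseController {
  Iir notch, quad;
  double env, decay, g, cos_psi, sin_psi;
  int counter, counter_limit;
  bool armed;
  double target, eps, rearm;
  // trigger-path smoothing: the raw in-phase/quadrature pair is vector-
  // averaged over a sliding window before the target comparison, which
  // suppresses spurious window entries from estimator jitter; the reported
  // phase stays unsmoothed.
  std::vector<double> zbuf, cbuf;
  double zsum, csum, adv_cos, adv_sin;
  int smooth_len, bufpos;
  bool buffull, progressed;

  void init(const List& cfg) {
    notch.init(cfg["notch_b"], cfg["notch_a"]);
    quad.init(cfg["quad_b"], cfg["quad_a"]);
    env = 0.0; counter = 0;
    decay = as<double>(cfg["env_decay"]);
    counter_limit = as<int>(cfg["env_counter_limit"]);
    g = as<double>(cfg["quad_gain"]);
    double psi = as<double>(cfg["quad_shift"]);
    cos_psi = std::cos(psi); sin_psi = std::sin(psi);
    armed = false;
    target = as<double>(cfg["target_deg"]);
    eps = as<double>(cfg["hysteresis_deg"]);
    rearm = as<double>(cfg["rearm_deg"]);
    smooth_len = as<int>(cfg["smooth_len"]);
    if (smooth_len < 1) smooth_len = 1;
    zbuf.assign(smooth_len, 0.0); cbuf.assign(smooth_len, 0.0);
    zsum = csum = 0.0; bufpos = 0; buffull = false;
    // the sliding average delays the phase by omega0*(W-1)/2; rotate the
    // averaged vector forward by the same angle so the trigger compares an
    // unlagged phase against the target
    double adv = as<double>(cfg["smooth_advance"]);
    adv_cos = std::cos(adv); adv_sin = std::sin(adv);
    progressed = true;
  }

  static double to_deg(double z, double c) {
    double phase = std::atan2(z, c) * 57.295779513082320877;
    if (phase < 0) phase += 360.0;
    return phase;
  }

  // one controller tick; returns the raw phase in degrees, sets *fire
  double step(double x, bool* fire, double* env_out) {
    double v = notch.step(x);
    double av = std::fabs(v);
    if (av >= env || counter >= counter_limit) { env = av; counter = 0; }
    else { env *= decay; ++counter; }
    double e = env > 1e-300 ? env : 1e-300;
    if (env_out) *env_out = env;
    double z = v / e;
    double y = quad.step(z);
    double c = (y / g - z * cos_psi) / sin_psi;
    double phase = to_deg(z, c);
    zsum += z - zbuf[bufpos]; zbuf[bufpos] = z;
    csum += c - cbuf[bufpos]; cbuf[bufpos] = c;
    if (++bufpos == smooth_len) { bufpos = 0; buffull = true; }
    double zr = zsum * adv_cos + csum * adv_sin;
    double cr = csum * adv_cos - zsum * adv_sin;
    double tphase = buffull ? to_deg(zr, cr) : phase;
    double d = std::fabs(tphase - target);
    if (d > 180.0) d = 360.0 - d;
    *fire = false;
    // one-shot per cycle: after a fire the trigger may re-arm only once the
    // phase has demonstrably traversed the opposite half-cycle, so estimator
    // jitter around the re-arm boundary cannot re-fire within the same cycle
    if (tphase >= 135.0 && tphase <= 270.0) progressed = true;
    if (armed && d <= eps) { *fire = true; armed = false; progressed = false; }
    else if (progressed && tphase >= rearm) { armed = true; }
    return phase;
  }
};

static inline double sigmoid(double V, double Qmax, double theta, double sigma_rho) {
  return Qmax / (1.0 + std::exp(-(V - theta) / sigma_rho));
}

// [[Rcpp::export]]
List nft_simulate_cpp(List par, List grid, double duration, int seed,
                      NumericVector dog, NumericVector pulse,
                      IntegerVector onset_steps, bool closed_loop,
                      Nullable<List> ctrl_cfg, List init_state,
                      double burn_in, bool store_fields,
                      int active_start_step, int active_end_step,
                      bool store_ctrl_trace) {
  const double alpha = as<double>(par["alpha"]);
  const double beta  = as<double>(par["beta"]);
  const double t0    = as<double>(par["t0"]);
  const double r_e   = as<double>(par["r_e"]);
  const double gam   = as<double>(par["gamma_e"]);
  const double Qmax  = as<double>(par["Q_max"]);
  const double theta = as<double>(par["theta"]);
  const double srho  = as<double>(par["sigma_rho"]);
  NumericVector nu   = par["nu"];           // V s, order ee ei es re rs se sr sn
  const double nu_ee = nu[0], nu_ei = nu[1], nu_es = nu[2], nu_re = nu[3];
  const double nu_rs = nu[4], nu_se = nu[5], nu_sr = nu[6], nu_sn = nu[7];
  const double phi_n0   = as<double>(par["phi_n0"]);
  const double noise_sd = as<double>(par["noise_sd"]);

  const int nx = as<int>(grid["nx"]);
  const int ny = as<int>(grid["ny"]);
  const int N  = nx * ny;
  const double side = as<double>(grid["side_length"]);
  const double dt   = as<double>(grid["dt"]);
  const int store_rate = as<int>(grid["store_rate"]);

  const double dx = side / nx;
  const double inv_dx2 = 1.0 / (dx * dx);
  const double re2 = r_e * r_e;
  const double ab = alpha * beta;
  const double apb = alpha + beta;
  const double gam2 = gam * gam;

  const int delay_steps = (int)std::lround(t0 / (2.0 * dt));
  const int burn_steps  = (int)std::lround(burn_in / dt);
  const long main_steps = (long)std::lround(duration / dt);
  const int decim = (int)std::lround(1.0 / (dt * store_rate));
  const long n_store = main_steps / decim;

  // state
  // Under the reduced-parameter convention the inhibitory population
  // receives exactly the cortical drive of the excitatory one and shares its
  // initial state, so V_i(t) == V_e(t) identically and Q_i == Q_e; it is not
  // integrated separately.
  std::vector<double> Ve(N, 0), We(N, 0),
      Vr(N, 0), Wr(N, 0), Vs(N, 0), Ws(N, 0),
      phie(N, 0), dphie(N, 0);
  double phie_init = 0.0, qs_init = 0.0;

  if (init_state.containsElementNamed("phi_e0")) {
    const double Ve0 = as<double>(init_state["V_e0"]);
    const double Vr0 = as<double>(init_state["V_r0"]);
    const double Vs0 = as<double>(init_state["V_s0"]);
    phie_init = as<double>(init_state["phi_e0"]);
    qs_init   = as<double>(init_state["phi_s0"]);
    for (int j = 0; j < N; ++j) {
      Ve[j] = Ve0; Vr[j] = Vr0; Vs[j] = Vs0;
      phie[j] = phie_init;
    }
  }

  // ring buffers (depth x N): past phi_e (for r,s inputs), past Q_s (for cortex)
  std::vector<double> buf_phie((size_t)delay_steps * N, phie_init);
  std::vector<double> buf_qs((size_t)delay_steps * N, qs_init);

  // neighbour index tables (toroidal)
  std::vector<int> ixl(N), ixr(N), ixu(N), ixd(N);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int j = y * nx + x;
      ixl[j] = y * nx + (x + nx - 1) % nx;
      ixr[j] = y * nx + (x + 1) % nx;
      ixu[j] = ((y + ny - 1) % ny) * nx + x;
      ixd[j] = ((y + 1) % ny) * nx + x;
    }

  GaussStream rng((uint64_t)(uint32_t)seed);

  // stimulation bookkeeping (step indices are relative to the main run)
  const int pulse_len = pulse.size();
  std::vector<long> onsets(onset_steps.begin(), onset_steps.end());
  size_t next_onset = 0;
  std::vector<std::pair<long,int> > active; // (start_step, consumed so far)

  PhaseController ctl;
  int ctrl_decim = 1;
  double ema = 0.0, ema_alpha = 0.0;
  bool ema_started = false;
  std::vector<long> cl_onsets;
  std::vector<double> tr_phase, tr_env;
  std::vector<int> tr_fire;
  if (closed_loop) {
    List cfg(ctrl_cfg);
    ctl.init(cfg);
    ctrl_decim = as<int>(cfg["decim"]);
    ema_alpha = as<double>(cfg["ema_alpha"]);
  }

  NumericVector xout(n_store);
  NumericMatrix fields;
  if (store_fields) fields = NumericMatrix(N, n_store);

  std::vector<double> Qe(N), Qr(N), Qs(N), phin(N), phie_new(N);

  long step_total = burn_steps + main_steps;
  for (long n = 0; n < step_total; ++n) {
    const bool in_main = n >= burn_steps;
    const long m = n - burn_steps;
    const int slot = (int)(n % delay_steps);
    double* dphie_buf = &buf_phie[(size_t)slot * N];
    double* dqs_buf   = &buf_qs[(size_t)slot * N];

    // firing rates at time t
    for (int j = 0; j < N; ++j) {
      Qe[j] = sigmoid(Ve[j], Qmax, theta, srho);
      Qr[j] = sigmoid(Vr[j], Qmax, theta, srho);
      Qs[j] = sigmoid(Vs[j], Qmax, theta, srho);
    }

    // input field: noise drawn every step so paired runs share the stream
    if (noise_sd > 0.0) {
      for (int j = 0; j < N; ++j) phin[j] = phi_n0 + noise_sd * rng.norm();
    } else {
      for (int j = 0; j < N; ++j) phin[j] = phi_n0;
    }

    double u_t = 0.0;
    if (in_main && pulse_len > 0) {
      while (next_onset < onsets.size() && onsets[next_onset] == m) {
        active.push_back(std::make_pair(m, 0));
        ++next_onset;
      }
      for (size_t q = 0; q < active.size();) {
        long k = m - active[q].first;
        if (k >= pulse_len) { active.erase(active.begin() + q); continue; }
        u_t += pulse[k];
        ++q;
      }
      if (u_t != 0.0)
        for (int j = 0; j < N; ++j) phin[j] += dog[j] * u_t;
    }

    // one Euler step (all RHS evaluated at time t)
    for (int j = 0; j < N; ++j) {
      const double phie_del = dphie_buf[j];
      const double qs_del   = dqs_buf[j];
      // refill the slot with the current values (read-before-write ring)
      dphie_buf[j] = phie[j];
      dqs_buf[j]   = Qs[j];

      const double De = nu_ee * phie[j] + nu_ei * Qe[j] + nu_es * qs_del;
      const double Dr = nu_re * phie_del + nu_rs * Qs[j];
      const double Ds = nu_se * phie_del + nu_sr * Qr[j] + nu_sn * phin[j];

      double v, w;
      v = Ve[j]; w = We[j];
      Ve[j] = v + dt * w; We[j] = w + dt * (ab * (De - v) - apb * w);
      v = Vr[j]; w = Wr[j];
      Vr[j] = v + dt * w; Wr[j] = w + dt * (ab * (Dr - v) - apb * w);
      v = Vs[j]; w = Ws[j];
      Vs[j] = v + dt * w; Ws[j] = w + dt * (ab * (Ds - v) - apb * w);
    }

    // damped wave propagation of phi_e (5-point toroidal Laplacian)
    {
      std::vector<double>& p = phie;
      for (int j = 0; j < N; ++j) {
        const double lap = (p[ixl[j]] + p[ixr[j]] + p[ixu[j]] + p[ixd[j]] - 4.0 * p[j]) * inv_dx2;
        const double acc = gam2 * (Qe[j] + re2 * lap - p[j]) - 2.0 * gam * dphie[j];
        phie_new[j] = p[j] + dt * dphie[j];
        dphie[j] += dt * acc;
      }
      p.swap(phie_new);
    }

    // instability guard
    if ((n & 127) == 127 || n + 1 == step_total) {
      for (int j = 0; j < N; ++j) {
        if (!std::isfinite(phie[j]) || std::fabs(phie[j]) > 10.0 * Qmax ||
            std::fabs(Ve[j]) > 1.0) {
          stop("numerical instability: field exceeded guard (reduce dt or check parameters)");
        }
      }
    }

    if (!in_main) continue;

    double mean_phie = 0.0;
    bool need_mean = (m % decim == 0) || (closed_loop && m % ctrl_decim == 0);
    if (need_mean) {
      for (int j = 0; j < N; ++j) mean_phie += phie[j];
      mean_phie /= N;
    }

    if (m % decim == 0) {
      long idx = m / decim;
      xout[idx] = mean_phie;
      if (store_fields)
        for (int j = 0; j < N; ++j) fields(j, idx) = phie[j];
    }

    if (closed_loop && m % ctrl_decim == 0) {
      if (!ema_started) { ema = mean_phie; ema_started = true; }
      ema += ema_alpha * (mean_phie - ema);
      bool fire = false; double envv = 0.0;
      double ph = ctl.step(mean_phie - ema, &fire, &envv);
      if (store_ctrl_trace && m % decim == 0) {
        tr_phase.push_back(ph); tr_env.push_back(envv); tr_fire.push_back(fire ? 1 : 0);
      }
      // the generator is busy while a pulse is playing: no retrigger before
      // the previous pulse has finished
      bool free_gen = cl_onsets.empty() ||
        (m + 1 - cl_onsets.back()) >= (long)pulse_len;
      if (fire && free_gen &&
          m + 1 >= active_start_step && m + 1 <= active_end_step) {
        cl_onsets.push_back(m + 1);
        active.push_back(std::make_pair(m + 1, 0));
      }
    }
  }

  List out = List::create(
    _["x_raw"] = xout,
    _["cl_onset_steps"] = wrap(cl_onsets));
  if (store_fields) out["phi_e_fields"] = fields;
  if (store_ctrl_trace)
    out["ctrl_trace"] = List::create(_["phase"] = wrap(tr_phase),
                                     _["envelope"] = wrap(tr_env),
                                     _["fire"] = wrap(tr_fire));
  return out;
}

// [[Rcpp::export]]
NumericMatrix nft_noise_stream_cpp(int seed, int n_steps, int n_nodes,
                                   double mean, double sd) {
  GaussStream rng((uint64_t)(uint32_t)seed);
  NumericMatrix out(n_nodes, n_steps);
  for (int t = 0; t < n_steps; ++t)
    for (int j = 0; j < n_nodes; ++j)
      out(j, t) = mean + sd * rng.norm();
  return out;
}

// [[Rcpp::export]]
List nft_controller_run_cpp(NumericVector x, List cfg) {
  PhaseController ctl;
  ctl.init(cfg);
  int n = x.size();
  NumericVector phase(n), env(n), z(n);
  LogicalVector fire(n);
  for (int i = 0; i < n; ++i) {
    bool f = false; double e = 0.0;
    phase[i] = ctl.step(x[i], &f, &e);
    env[i] = e; fire[i] = f;
  }
  return List::create(_["phase"] = phase, _["envelope"] = env, _["fire"] = fire);
}
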