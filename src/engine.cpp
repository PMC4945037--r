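// Simulation core: leaky integrate-and-fire surrogate of the
// subthalamopallidal circuit, a phase-oscillator population backend, and an
// incremental time-weighted Fourier phase tracker driving the closed loop.
//
// All randomness comes from R's RNG (seeded from R with set.seed), so runs
// are bitwise reproducible for a fixed seed.

#include <Rcpp.h>
#include <deque>
#include <complex>
#include <vector>
#include <cmath>
#include <algorithm>
#include <random>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925287;

// ---------------------------------------------------------------------------
// Incremental tracker for X(f,t) = sum_k exp((S_k - t)/tau) exp(-2*pi*i f S_k)
// over spikes in [t - T, t].  Exact: expired spikes are subtracted with the
// weight they currently carry (the decay factor accumulates multiplicatively,
// matching exp((S_k - t)/tau) in real arithmetic).
// ---------------------------------------------------------------------------
struct Tracker {
  std::vector<double> freq;                 // Hz
  double tau, T;                            // ms
  double t;                                 // current evaluation time (ms)
  std::vector< std::complex<double> > X;
  std::deque<double> win;                   // spike times inside window

  Tracker(const std::vector<double>& f, double tau_, double T_, double t0)
    : freq(f), tau(tau_), T(T_), t(t0), X(f.size(), std::complex<double>(0, 0)) {}

  inline std::complex<double> carrier(double f_hz, double s_ms) const {
    double a = -TWO_PI * f_hz * s_ms / 1000.0;
    return std::complex<double>(std::cos(a), std::sin(a));
  }

  // advance to t2 >= t, feeding spikes with times in (t, t2] (sorted)
  void advance(double t2, const std::vector<double>& spikes) {
    double decay = std::exp(-(t2 - t) / tau);
    for (size_t i = 0; i < X.size(); ++i) X[i] *= decay;
    for (size_t k = 0; k < spikes.size(); ++k) {
      double s = spikes[k];
      double w = std::exp((s - t2) / tau);
      for (size_t i = 0; i < freq.size(); ++i) X[i] += w * carrier(freq[i], s);
      win.push_back(s);
    }
    while (!win.empty() && win.front() < t2 - T) {
      double s = win.front(); win.pop_front();
      double w = std::exp((s - t2) / tau);
      for (size_t i = 0; i < freq.size(); ++i) X[i] -= w * carrier(freq[i], s);
    }
    t = t2;
  }

  // instantaneous phase in cycles [0,1); false if no spikes in window
  bool phase(double& phi) const {
    if (win.empty()) { phi = NA_REAL; return false; }
    std::complex<double> z(0, 0);
    for (size_t i = 0; i < freq.size(); ++i) {
      double a = TWO_PI * freq[i] * t / 1000.0;
      z += X[i] * std::complex<double>(std::cos(a), std::sin(a));
    }
    double p = std::arg(z) / TWO_PI;
    p -= std::floor(p);
    if (p >= 1.0) p = 0.0;
    phi = p;
    return true;
  }
};

// ---------------------------------------------------------------------------
// Closed-loop controller shared by both backends.
// ---------------------------------------------------------------------------
struct PendingPulse {
  double t_on;
  double amp;     // fraction of reference amplitude
  double width;   // ms
  int    k;       // index within burst (0 = first)
};

struct ClosedLoop {
  bool enabled = false;       // tracker running
  bool stimulate = false;     // triggers emit pulses
  Tracker* trk = nullptr;
  double eval_dt = 0.5, start = 400.0, lockout = 14.7;
  double delay = 0.0, isi = 5.0, amp = 0.1, width = 0.5;
  int n_pulses = 1;
  bool volley = false;
  double deadlock_ms = 0.0;   // 0 = disabled
  // state
  double phi_prev = NA_REAL;
  bool   valid_prev = false;
  double last_trigger = R_NegInf;
  double last_activity = 0.0;
  std::deque<PendingPulse> pending;
  // outputs
  std::vector<double> triggers;
  std::vector<double> trace_t, trace_phi;
  std::vector<int> trace_valid, trace_n;
  bool record_trace = false;

  // process one evaluation at time t2 with this chunk's oscillator spikes;
  // returns trigger time (or NA)
  double evaluate(double t2, const std::vector<double>& chunk) {
    trk->advance(t2, chunk);
    double phi;
    bool ok = trk->phase(phi);
    double tc = NA_REAL;
    if (ok && valid_prev && (phi_prev - phi) > 0.5) {
      // wrap from near 1 down through 0: sub-grid linear interpolation
      double frac = (1.0 - phi_prev) / ((phi + 1.0) - phi_prev);
      double cross = (t2 - eval_dt) + frac * eval_dt;
      if (cross - last_trigger >= lockout) {
        last_trigger = cross;
        tc = cross;
        triggers.push_back(cross);
        if (stimulate) {
          // truncate any still-pending pulses from the previous burst
          while (!pending.empty() && pending.back().t_on > cross) pending.pop_back();
          for (int k = 0; k < n_pulses; ++k) {
            PendingPulse p;
            p.t_on = std::max(cross + delay + k * isi, t2);
            p.amp = amp; p.width = width; p.k = k;
            pending.push_back(p);
          }
        }
      }
    }
    if (record_trace) {
      trace_t.push_back(t2);
      trace_phi.push_back(ok ? phi : NA_REAL);
      trace_valid.push_back(ok ? 1 : 0);
      trace_n.push_back((int) trk->win.size());
    }
    phi_prev = phi; valid_prev = ok;
    return tc;
  }

  double current_phase_valid() const {
    return valid_prev ? phi_prev : NA_REAL;
  }
};

static ClosedLoop make_closed_loop(List cl, Tracker** trk_out) {
  ClosedLoop c;
  std::string mode = as<std::string>(cl["mode"]);  // "none", "track", "stim"
  if (mode == "none") return c;
  std::vector<double> freqs = as< std::vector<double> >(cl["freqs"]);
  double tau = as<double>(cl["tau"]);
  double T = as<double>(cl["T"]);
  c.start = as<double>(cl["start"]);
  *trk_out = new Tracker(freqs, tau, T, c.start);
  c.trk = *trk_out;
  c.enabled = true;
  c.stimulate = (mode == "stim");
  c.eval_dt = as<double>(cl["eval_dt"]);
  c.lockout = as<double>(cl["lockout"]);
  c.deadlock_ms = as<double>(cl["deadlock_ms"]);
  c.record_trace = as<bool>(cl["record_trace"]);
  if (c.stimulate) {
    c.delay = as<double>(cl["delay"]);
    c.isi = as<double>(cl["isi"]);
    c.amp = as<double>(cl["amp"]);
    c.width = as<double>(cl["width"]);
    c.n_pulses = as<int>(cl["n_pulses"]);
    c.volley = as<bool>(cl["volley"]);
  }
  c.last_activity = c.start;
  return c;
}

// ---------------------------------------------------------------------------
// Spiking network backend
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_network_cpp(List cfg, double duration, NumericMatrix stim, List cl_in,
                     List structure) {
  // --- unpack configuration -------------------------------------------------
  const int n_stn = as<int>(cfg["n_stn"]);
  const int n_gpe = as<int>(cfg["n_gpe"]);
  const int n_gpi = as<int>(cfg["n_gpi"]);
  const int N = n_stn + n_gpe + n_gpi;
  const int off_stn = 0, off_gpe = n_stn, off_gpi = n_stn + n_gpe;
  const double dt = as<double>(cfg["dt"]);

  const double EL = as<double>(cfg["E_leak"]);
  const double EE = as<double>(cfg["E_exc"]);
  const double EI = as<double>(cfg["E_inh"]);
  const double Vth = as<double>(cfg["V_thresh"]);
  const double Vre = as<double>(cfg["V_reset"]);
  const double tref = as<double>(cfg["t_ref"]);
  const double tau_e = as<double>(cfg["tau_exc"]);
  const double tau_i = as<double>(cfg["tau_inh"]);
  NumericVector tau_m_pop = cfg["tau_m"];       // length 3: STN, GPe, GPi
  NumericVector bias_mean = cfg["bias_mean"];   // length 3
  NumericVector bias_sd = cfg["bias_sd"];       // length 3

  List ctx = cfg["cortical_drive"];
  const double ctx_hz = as<double>(ctx["rate_hz"]);          // 16 Hz cycle
  const double ctx_burst_frac = as<double>(ctx["burst_frac"]);
  const double ctx_rate_burst = as<double>(ctx["rate_burst"]); // Hz per neuron
  const double ctx_rate_base = as<double>(ctx["rate_base"]);
  const double ctx_gain_sd = as<double>(ctx["gain_sd"]);     // lognormal sigma
  const double w_ctx = as<double>(ctx["w"]);

  List str = cfg["striatal_drive"];
  const double str_rate_gpe = as<double>(str["rate_gpe"]);
  const double str_rate_gpi = as<double>(str["rate_gpi"]);
  const double w_str = as<double>(str["w"]);

  List bg = cfg["background"];
  const double bg_rate = as<double>(bg["rate"]);
  const double w_bg = as<double>(bg["w"]);

  List st = cfg["stim"];
  const double ref_amp = as<double>(st["ref_amp"]);     // mV drive at amp = 1
  const double w_volley = as<double>(st["w_volley"]);
  const double volley_delay = as<double>(st["volley_delay"]);

  // --- connectivity and per-neuron structure (built in R) -------------------
  // edges: 1-based src/tgt (absolute indices), weight, delay (ms), inh flag
  IntegerVector e_src = structure["src"];
  IntegerVector e_tgt = structure["tgt"];
  NumericVector e_w = structure["w"];
  NumericVector e_dly = structure["delay"];
  IntegerVector e_inh = structure["inh"];
  NumericVector st_bias = structure["bias"];
  NumericVector st_V0 = structure["V0"];
  if ((int) st_bias.size() != N || (int) st_V0.size() != N)
    stop("structure does not match the population sizes");

  const size_t n_edges = e_src.size();
  const double inv_dt = 1.0 / dt;
  std::vector<int> syn_ptr(N + 1, 0);
  std::vector<int> syn_tgt(n_edges); std::vector<double> syn_w(n_edges);
  std::vector<int> syn_dly(n_edges); std::vector<char> syn_inh(n_edges);
  for (size_t i = 0; i < n_edges; ++i) syn_ptr[e_src[i]]++;  // src is 1-based
  for (int i = 0; i < N; ++i) syn_ptr[i + 1] += syn_ptr[i];
  {
    std::vector<int> fill(syn_ptr.begin(), syn_ptr.end() - 1);
    for (size_t i = 0; i < n_edges; ++i) {
      int pos = fill[e_src[i] - 1]++;
      syn_tgt[pos] = e_tgt[i] - 1; syn_w[pos] = e_w[i];
      int d = (int) std::lround(e_dly[i] * inv_dt); if (d < 1) d = 1;
      syn_dly[pos] = d; syn_inh[pos] = (char) e_inh[i];
    }
  }

  int max_dly = 1;
  for (size_t i = 0; i < syn_dly.size(); ++i) max_dly = std::max(max_dly, syn_dly[i]);
  int vdly = (int) std::lround(volley_delay * inv_dt); if (vdly < 1) vdly = 1;
  max_dly = std::max(max_dly, vdly);
  const int L = max_dly + 1;
  std::vector<double> bufE((size_t) L * N, 0.0), bufI((size_t) L * N, 0.0);

  // --- state ----------------------------------------------------------------
  std::vector<double> V(N), gE(N, 0.0), gI(N, 0.0), bias(N), ref_until(N, -1.0), tau_m(N);
  for (int i = 0; i < N; ++i) {
    int p = (i < off_gpe) ? 0 : (i < off_gpi ? 1 : 2);
    tau_m[i] = tau_m_pop[p];
    bias[i] = st_bias[i];
    V[i] = st_V0[i];
  }

  const double decE = std::exp(-dt / tau_e), decI = std::exp(-dt / tau_i);

  // Poisson input state (exponential gaps, rates in events/ms)
  const double r_bg = bg_rate / 1000.0;
  const double r_str_gpe = str_rate_gpe / 1000.0;
  const double r_str_gpi = str_rate_gpi / 1000.0;
  std::vector<double> next_bg(N), next_str(N, R_PosInf), next_ctx(N, R_PosInf);
  for (int i = 0; i < N; ++i)
    next_bg[i] = (r_bg > 0) ? exp_rand() / r_bg : R_PosInf;
  for (int i = off_gpe; i < off_gpi; ++i)
    next_str[i] = (r_str_gpe > 0) ? exp_rand() / r_str_gpe : R_PosInf;
  for (int i = off_gpi; i < N; ++i)
    next_str[i] = (r_str_gpi > 0) ? exp_rand() / r_str_gpi : R_PosInf;

  // cortical 16 Hz stochastic bursting drive (piecewise-constant rate)
  const double cyc_len = 1000.0 / ctx_hz;
  const double burst_len = ctx_burst_frac * cyc_len;
  double seg_end = 0.0, ctx_rate = 0.0;   // current segment
  bool in_burst = false; double cyc_gain = 1.0; double cyc_start = 0.0;
  auto resample_ctx = [&](double from) {
    double r = ctx_rate / 1000.0;
    for (int i = 0; i < n_stn; ++i)
      next_ctx[i] = (r > 0) ? from + exp_rand() / r : R_PosInf;
  };
  // initialise first cycle
  cyc_gain = std::exp(ctx_gain_sd * norm_rand() - 0.5 * ctx_gain_sd * ctx_gain_sd);
  in_burst = (burst_len > 0);
  ctx_rate = in_burst ? ctx_rate_burst * cyc_gain : ctx_rate_base;
  seg_end = in_burst ? burst_len : cyc_len;
  resample_ctx(0.0);

  // --- stimulation events ---------------------------------------------------
  // external events: columns t_on, amp(frac), width, volley(0/1)
  const int n_ext = stim.nrow();
  int ext_i = 0;
  struct Active { double t_off; double amp; };
  std::vector<Active> active;
  std::deque<PendingPulse> ext_pending;  // not used; external handled by index

  Tracker* trk = nullptr;
  ClosedLoop cl = make_closed_loop(cl_in, &trk);

  // outputs
  std::vector<int> sp_pop, sp_nrn; std::vector<double> sp_t;
  sp_t.reserve(100000);
  std::vector<double> out_stim_t, out_stim_amp, out_stim_w, out_stim_phase;
  std::vector<int> out_stim_k;

  const long nsteps = (long) std::lround(duration / dt);
  const long eval_every = cl.enabled ? std::max(1L, (long) std::lround(cl.eval_dt / dt)) : 0;
  std::vector<double> chunk_spikes;  // GPe spikes since last evaluation

  double Istim = 0.0;
  int slot = 0;

  auto deliver_onset = [&](double t_on, double amp, double width, bool volley, int k) {
    // record; start current; optional efferent synaptic volley to GPe/GPi
    out_stim_t.push_back(t_on); out_stim_amp.push_back(amp);
    out_stim_w.push_back(width); out_stim_k.push_back(k);
    out_stim_phase.push_back(cl.enabled ? cl.current_phase_valid() : NA_REAL);
    Active a; a.t_off = t_on + width; a.amp = amp * ref_amp; active.push_back(a);
    Istim += a.amp;
    if (volley && w_volley > 0) {
      int s = ((slot + vdly) % L);
      for (int i = off_gpe; i < N; ++i) bufE[(size_t) s * N + i] += w_volley * amp;
    }
  };

  for (long stepi = 0; stepi < nsteps; ++stepi) {
    const double t = stepi * dt, tn = t + dt;

    // cortical rate segments
    while (tn > seg_end) {
      double from = seg_end;
      if (in_burst) { in_burst = false; ctx_rate = ctx_rate_base; seg_end = cyc_start + cyc_len; }
      else {
        cyc_start += cyc_len;
        cyc_gain = std::exp(ctx_gain_sd * norm_rand() - 0.5 * ctx_gain_sd * ctx_gain_sd);
        in_burst = (burst_len > 0);
        ctx_rate = in_burst ? ctx_rate_burst * cyc_gain : ctx_rate_base;
        seg_end = cyc_start + (in_burst ? burst_len : cyc_len);
      }
      resample_ctx(from);
    }

    // stimulus onsets due in (t, tn]
    while (ext_i < n_ext && stim(ext_i, 0) <= tn) {
      deliver_onset(stim(ext_i, 0), stim(ext_i, 1), stim(ext_i, 2),
                    stim(ext_i, 3) != 0.0, 0);
      ++ext_i;
    }
    while (!cl.pending.empty() && cl.pending.front().t_on <= tn) {
      PendingPulse p = cl.pending.front(); cl.pending.pop_front();
      deliver_onset(p.t_on, p.amp, p.width, cl.volley, p.k);
    }
    // expire finished pulses
    if (!active.empty()) {
      for (size_t a = 0; a < active.size(); ) {
        if (active[a].t_off <= t) { Istim -= active[a].amp; active[a] = active.back(); active.pop_back(); }
        else ++a;
      }
      if (active.empty()) Istim = 0.0;  // kill accumulated rounding
    }

    const size_t base = (size_t) slot * N;
    // conductance decay + delayed synaptic arrivals (branch-free, SIMD-able)
    for (int i = 0; i < N; ++i) {
      gE[i] = gE[i] * decE + bufE[base + i];
      gI[i] = gI[i] * decI + bufI[base + i];
      bufE[base + i] = 0.0; bufI[base + i] = 0.0;
    }
    // Poisson inputs (rare bodies; kept in source order for RNG stability)
    for (int i = 0; i < N; ++i) {
      while (next_bg[i] <= tn) { gE[i] += w_bg; next_bg[i] += exp_rand() / r_bg; }
      if (i >= off_gpe) {
        double r = (i < off_gpi) ? r_str_gpe : r_str_gpi;
        while (next_str[i] <= tn) { gI[i] += w_str; next_str[i] += exp_rand() / r; }
      } else {
        while (next_ctx[i] <= tn) {
          gE[i] += w_ctx * 1.0;
          double r = ctx_rate / 1000.0;
          next_ctx[i] = (r > 0) ? next_ctx[i] + exp_rand() / r : R_PosInf;
        }
      }
    }
    // membrane update (branch-free select keeps refractory neurons at reset)
    for (int i = 0; i < N; ++i) {
      double drive = bias[i] + (i < off_gpe ? Istim : 0.0);
      double v = V[i];
      v += (dt / tau_m[i]) * (-(v - EL) - gE[i] * (v - EE) - gI[i] * (v - EI) + drive);
      V[i] = (tn < ref_until[i]) ? Vre : v;
    }
    // threshold crossings (rare)
    for (int i = 0; i < N; ++i) {
      double v = V[i];
      if (v >= Vth) {
        if (!(v < 1e6))
          stop("non-finite membrane potential at t = %f ms (neuron %d)", tn, i + 1);
        V[i] = Vre; ref_until[i] = tn + tref;
        int pop = (i < off_gpe) ? 0 : (i < off_gpi ? 1 : 2);
        sp_pop.push_back(pop);
        sp_nrn.push_back(i - (pop == 0 ? off_stn : (pop == 1 ? off_gpe : off_gpi)) + 1);
        sp_t.push_back(tn);
        if (pop == 1 && cl.enabled) chunk_spikes.push_back(tn);
        for (int s = syn_ptr[i]; s < syn_ptr[i + 1]; ++s) {
          size_t pos = (size_t) ((slot + syn_dly[s]) % L) * N + syn_tgt[s];
          if (syn_inh[s]) bufI[pos] += syn_w[s]; else bufE[pos] += syn_w[s];
        }
      } else if (!(v > -1e6) || !(v < 1e6)) {
        stop("non-finite membrane potential at t = %f ms (neuron %d)", tn, i + 1);
      }
    }

    // closed-loop evaluation
    if (cl.enabled && eval_every > 0 && ((stepi + 1) % eval_every == 0) && tn >= cl.start) {
      double tc = cl.evaluate(tn, chunk_spikes);
      chunk_spikes.clear();
      if (!ISNA(tc)) cl.last_activity = tc;
      if (cl.deadlock_ms > 0 && tn - cl.last_activity > cl.deadlock_ms)
        stop("closed-loop deadlock: no trigger for %.0f ms (t = %.1f ms, %d spikes in window)",
             cl.deadlock_ms, tn, (int) cl.trk->win.size());
    }

    slot = (slot + 1) % L;
    if ((stepi & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["pop"] = wrap(sp_pop), _["neuron"] = wrap(sp_nrn), _["t"] = wrap(sp_t),
    _["stim_t"] = wrap(out_stim_t), _["stim_amp"] = wrap(out_stim_amp),
    _["stim_width"] = wrap(out_stim_w), _["stim_k"] = wrap(out_stim_k),
    _["stim_phase"] = wrap(out_stim_phase),
    _["triggers"] = wrap(cl.triggers));
  if (cl.record_trace)
    out["trace"] = DataFrame::create(
      _["t"] = wrap(cl.trace_t), _["phi"] = wrap(cl.trace_phi),
      _["valid"] = wrap(cl.trace_valid), _["n_spikes"] = wrap(cl.trace_n));
  if (trk) delete trk;
  return out;
}

// ---------------------------------------------------------------------------
// Phase-oscillator population backend.  Oscillators advance at 1/period
// cycles per ms, fire when phase crosses 1, receive per-cycle Gaussian phase
// jitter at each wrap, and are kicked by prc(phi) (linearly interpolated,
// periodic) scaled by amp/amp_ref at each stimulus.
// ---------------------------------------------------------------------------
struct PhasePop {
  int n;
  double period, jitter;
  std::vector<double> phi;
  std::vector<double> prc;   // values at k/m, k = 0..m-1
  double amp_ref;
  std::vector<int>* sp_id; std::vector<double>* sp_t;
  // per-oscillator RNG streams: the jitter an oscillator receives on its
  // k-th cycle is independent of what happens to the other oscillators, so
  // stimulation cannot reorder the draws
  std::vector<std::mt19937> rng;

  // stateless standard normal (Box-Muller without the cached spare, so a
  // draw consumes a fixed amount of the oscillator's stream)
  double gauss(std::mt19937& g) {
    double u1 = (g() + 0.5) / 4294967296.0;
    double u2 = (g() + 0.5) / 4294967296.0;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(TWO_PI * u2);
  }

  void seed_streams() {
    rng.resize(n);
    for (int i = 0; i < n; ++i) {
      uint32_t s = (uint32_t) std::floor(unif_rand() * 4294967295.0);
      rng[i].seed(s);
    }
  }

  double prc_at(double p) const {
    int m = (int) prc.size();
    double x = p - std::floor(p);
    double g = x * m;
    int k = (int) std::floor(g);
    double fr = g - k;
    int k2 = (k + 1) % m;
    return prc[k % m] * (1.0 - fr) + prc[k2] * fr;
  }

  void fire(int i, double tw) {
    sp_id->push_back(i + 1);
    sp_t->push_back(tw);
  }

  // advance all oscillators from t1 to t2 (no stimuli inside)
  void advance(double t1, double t2) {
    for (int i = 0; i < n; ++i) {
      double ti = t1, p = phi[i];
      for (;;) {
        double tw = ti + (1.0 - p) * period;
        if (tw > t2 || tw <= ti) {  // tw<=ti guards p>=1 after big kicks
          if (tw <= ti) { fire(i, ti); p -= 1.0; continue; }
          p += (t2 - ti) / period;
          break;
        }
        fire(i, tw);
        ti = tw;
        p = (jitter > 0) ? jitter * gauss(rng[i]) : 0.0;
      }
      phi[i] = p;
    }
  }

  void kick(double t_at, double amp) {
    double scale = (amp_ref > 0) ? amp / amp_ref : 1.0;
    for (int i = 0; i < n; ++i) {
      double p = phi[i];
      double k = scale * prc_at(p);
      if (!std::isfinite(k)) stop("PRC returned a non-finite phase advance");
      p += k;
      while (p >= 1.0) { fire(i, t_at); p -= 1.0; }
      phi[i] = p;
    }
  }
};

// [[Rcpp::export]]
List sim_phasepop_cpp(List cfg, double duration, NumericMatrix stim, List cl_in) {
  PhasePop pp;
  pp.phi = as< std::vector<double> >(cfg["phases"]);
  pp.n = (int) pp.phi.size();
  pp.period = as<double>(cfg["period"]);
  pp.jitter = as<double>(cfg["jitter_sd"]);
  pp.prc = as< std::vector<double> >(cfg["prc"]);
  pp.amp_ref = as<double>(cfg["amp_ref"]);
  pp.seed_streams();
  std::vector<int> sp_id; std::vector<double> sp_t;
  pp.sp_id = &sp_id; pp.sp_t = &sp_t;

  Tracker* trk = nullptr;
  ClosedLoop cl = make_closed_loop(cl_in, &trk);

  std::vector<double> out_stim_t, out_stim_amp, out_stim_w, out_stim_phase;
  std::vector<int> out_stim_k;

  const int n_ext = stim.nrow();
  int ext_i = 0;
  double t = 0.0;
  size_t sp_done = 0;   // spikes already fed to the tracker

  auto deliver = [&](double t_on, double amp, double width, int k) {
    // events between t and t_on: advance, then kick
    pp.advance(t, t_on); t = t_on;
    out_stim_t.push_back(t_on); out_stim_amp.push_back(amp);
    out_stim_w.push_back(width); out_stim_k.push_back(k);
    out_stim_phase.push_back(cl.enabled ? cl.current_phase_valid() : NA_REAL);
    pp.kick(t_on, amp);
  };

  if (!cl.enabled) {
    for (int e = 0; e < n_ext; ++e)
      deliver(stim(e, 0), stim(e, 1), stim(e, 2), 0);
    pp.advance(t, duration);
  } else {
    const double eval_dt = cl.eval_dt;
    long nchunks = (long) std::ceil(duration / eval_dt);
    for (long c = 0; c < nchunks; ++c) {
      double tn = std::min((c + 1) * eval_dt, duration);
      // deliver stimuli due in (t, tn]
      for (;;) {
        double next_ext = (ext_i < n_ext) ? stim(ext_i, 0) : R_PosInf;
        double next_cl = (!cl.pending.empty()) ? cl.pending.front().t_on : R_PosInf;
        double nxt = std::min(next_ext, next_cl);
        if (nxt > tn) break;
        if (next_ext <= next_cl) {
          deliver(stim(ext_i, 0), stim(ext_i, 1), stim(ext_i, 2), 0); ++ext_i;
        } else {
          PendingPulse p = cl.pending.front(); cl.pending.pop_front();
          deliver(p.t_on, p.amp, p.width, p.k);
        }
      }
      pp.advance(t, tn); t = tn;
      if (tn >= cl.start) {
        // feed new spikes (sorted) to the tracker
        std::vector<double> chunk(sp_t.begin() + sp_done, sp_t.end());
        std::sort(chunk.begin(), chunk.end());
        sp_done = sp_t.size();
        double tc = cl.evaluate(tn, chunk);
        if (!ISNA(tc)) cl.last_activity = tc;
        if (cl.deadlock_ms > 0 && tn - cl.last_activity > cl.deadlock_ms)
          stop("closed-loop deadlock: no trigger for %.0f ms (t = %.1f ms)",
               cl.deadlock_ms, tn);
      }
      if ((c & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
    _["neuron"] = wrap(sp_id), _["t"] = wrap(sp_t),
    _["phases_end"] = wrap(pp.phi),
    _["stim_t"] = wrap(out_stim_t), _["stim_amp"] = wrap(out_stim_amp),
    _["stim_width"] = wrap(out_stim_w), _["stim_k"] = wrap(out_stim_k),
    _["stim_phase"] = wrap(out_stim_phase),
    _["triggers"] = wrap(cl.triggers));
  if (cl.record_trace)
    out["trace"] = DataFrame::create(
      _["t"] = wrap(cl.trace_t), _["phi"] = wrap(cl.trace_phi),
      _["valid"] = wrap(cl.trace_valid), _["n_spikes"] = wrap(cl.trace_n));
  if (trk) delete trk;
  return out;
}

// ---------------------------------------------------------------------------
// Stand-alone phase trace over a time grid from a sorted spike-time vector.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame phase_trace_cpp(NumericVector spike_times, double t_start, double t_end,
                          double eval_dt, NumericVector freqs, double tau, double T) {
  std::vector<double> f = as< std::vector<double> >(freqs);
  Tracker trk(f, tau, T, t_start - T);  // start far enough back to load window
  // preload spikes up to t_start via a single advance
  size_t idx = 0;
  const size_t ns = spike_times.size();
  {
    std::vector<double> pre;
    while (idx < ns && spike_times[idx] <= t_start) pre.push_back(spike_times[idx++]);
    // two-stage: move tracker to t_start feeding the preload
    trk.advance(t_start, pre);
  }
  long n = (long) std::floor((t_end - t_start) / eval_dt + 1e-9) + 1;
  std::vector<double> out_t(n), out_phi(n);
  std::vector<int> out_valid(n), out_n(n);
  for (long k = 0; k < n; ++k) {
    double t2 = t_start + k * eval_dt;
    if (k > 0) {
      std::vector<double> chunk;
      while (idx < ns && spike_times[idx] <= t2) chunk.push_back(spike_times[idx++]);
      trk.advance(t2, chunk);
    }
    double phi; bool ok = trk.phase(phi);
    out_t[k] = t2; out_phi[k] = ok ? phi : NA_REAL;
    out_valid[k] = ok ? 1 : 0; out_n[k] = (int) trk.win.size();
  }
  return DataFrame::create(_["t"] = wrap(out_t), _["phi"] = wrap(out_phi),
                           _["valid"] = wrap(out_valid), _["n_spikes"] = wrap(out_n));
}
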