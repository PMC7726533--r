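// Closed-loop simulation kernel: conductance-based LIF neuron driven by
// OU-modulated Poisson afferents (or pulse / fixed-raster input), with
// optional online inhibitory plasticity and online input/output
// correlation accumulation.
//
// Discrete scheme (identical to the pure-R reference in R/lif.R):
// per step: decay conductances (Euler factor), add arriving weight
// increments, Euler-update the voltage, test the threshold; the voltage is
// clamped at u_reset during the refractory period while conductances keep
// evolving.  Postsynaptic spike times are (step index + 1) * dt.
//
// Presynaptic spikes are per-step Bernoulli draws with probability
// rate * dt, suppressed for the per-class refractory period.  Rates are
// piecewise constant on the OU update grid, which allows exact geometric
// jump sampling within each block instead of one uniform draw per step.
//
// Plasticity traces decay by the exact factor exp(-dt/tau_STDP); weight
// updates at a spike read trace values before the current spike's own +1
// increment.  The scaling rule is accumulated in exact affine form
// (multiplicative LTD, additive LTP are jointly affine in w) and
// materialised lazily.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Trace {
  std::vector<double> val;
  std::vector<long> last;
  double dt, tau;
  void init(int n, double dt_, double tau_) {
    val.assign(n, 0.0);
    last.assign(n, 0L);
    dt = dt_;
    tau = tau_;
  }
  double at(int j, long s) const {
    return val[j] * std::exp(-(double)(s - last[j]) * dt / tau);
  }
  void bump(int j, long s) {
    val[j] = at(j, s) + 1.0;
    last[j] = s;
  }
};

inline double safe_unif() {
  double u = R::unif_rand();
  if (u <= 0.0) u = 1e-300;
  if (u >= 1.0) u = 1.0 - 1e-16;
  return u;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List args) {
  // --- neuron parameters -------------------------------------------------
  List neuron = args["neuron"];
  const double tau_m = neuron["tau_m"], u_rest = neuron["u_rest"];
  const double E_E = neuron["E_E"], E_I = neuron["E_I"];
  const double tau_E = neuron["tau_E"], tau_I = neuron["tau_I"];
  const double u_th = neuron["u_th"], u_reset = neuron["u_reset"];
  const double tau_ref = neuron["tau_ref"], dt = neuron["dt"];
  const double duration = args["duration"];
  const long n_steps = (long)std::llround(duration / dt);
  const double decE = 1.0 - dt / tau_E, decI = 1.0 - dt / tau_I;
  const long ref_steps = (long)std::llround(tau_ref / dt);

  // --- architecture and weights -----------------------------------------
  IntegerVector group = args["group"];  // 1-based
  IntegerVector pop = args["pop"];      // 0 exc, 1..n_pops inhibitory
  const int n = group.size();
  const int n_groups = as<int>(args["n_groups"]);
  const int n_pops = as<int>(args["n_inh_pops"]);
  std::vector<double> w(as<std::vector<double>>(args["w"]));
  if ((int)w.size() != n) stop("kernel: weight vector length mismatch");

  // --- input mode --------------------------------------------------------
  const std::string mode = as<std::string>(args["input_mode"]);
  List input = args["input"];
  NumericVector gains = input.containsElementNamed("gains")
                            ? as<NumericVector>(input["gains"])
                            : NumericVector(n_pops, 1.0);
  if (gains.size() != n_pops) stop("kernel: gains length mismatch");

  double dT = 1.0, tau_OU = 50.0;
  double nu_E0 = 0, nu_Ebg = 0, nu_I0 = 0, nu_Ibg = 0;
  long ref_steps_E = 0, ref_steps_I = 0;
  double pulse_onset = 0, pulse_dur = 0, pulse_ampE = 0, pulse_ampI = 0;
  int pulse_group = 0;
  if (mode == "natural" || mode == "pulse") {
    dT = as<double>(input["dT"]);
    nu_Ebg = as<double>(input["nu_Ebg"]);
    nu_Ibg = as<double>(input["nu_Ibg"]);
    ref_steps_E = (long)std::llround(as<double>(input["tau_Eref"]) / dt);
    ref_steps_I = (long)std::llround(as<double>(input["tau_Iref"]) / dt);
    if (mode == "natural") {
      tau_OU = as<double>(input["tau_OU"]);
      nu_E0 = as<double>(input["nu_E0"]);
      nu_I0 = as<double>(input["nu_I0"]);
    } else {
      pulse_onset = as<double>(input["onset"]);
      pulse_dur = as<double>(input["pulse_duration"]);
      pulse_group = as<int>(input["target_group"]);
      const double k = as<double>(input["k"]), nu_star = as<double>(input["nu_star"]);
      pulse_ampE = as<double>(input["alpha_E"]) * k * nu_star;
      pulse_ampI = as<double>(input["alpha_I"]) * k * nu_star;
    }
  }
  IntegerVector raster_step, raster_id;
  if (mode == "raster") {
    raster_step = as<IntegerVector>(input["step"]);  // 1-based step
    raster_id = as<IntegerVector>(input["afferent"]);
  }

  // --- plasticity --------------------------------------------------------
  List plast = args["plasticity"];
  const bool plast_on = as<bool>(plast["enabled"]);
  // rule codes per inhibitory population: 0 none/fixed, 1 hebbian,
  // 2 scaling, 3 anti-hebbian
  IntegerVector rule = as<IntegerVector>(plast["rule"]);
  if (rule.size() != n_pops) stop("kernel: rule length mismatch");
  const double tau_stdp = as<double>(plast["tau_STDP"]);
  const double eta_H = as<double>(plast["eta_H"]);
  const double alpha_H = as<double>(plast["alpha_H"]);
  const double eta_s_eff = as<double>(plast["eta_s_eff"]);  // per ms
  const double w_Is = as<double>(plast["w_Is"]);
  const double rho_0 = as<double>(plast["rho_0"]);
  const double alpha_s = as<double>(plast["alpha_s"]);
  const double tau_sc = as<double>(plast["tau_scaling"]);
  const double eta_aH0 = as<double>(plast["eta_aH_star"]);
  const double tau_aH = as<double>(plast["tau_aH"]);
  const double alpha_aH = as<double>(plast["alpha_aH"]);
  const double t0_aH = as<double>(plast["t0"]);
  const double dec_sc = std::exp(-dt / tau_sc);
  const double y_jump = 1000.0 / tau_sc;  // Hz per postsynaptic spike
  double y_post = as<double>(plast["y_post0"]);

  std::vector<std::vector<int>> members(n_pops);
  for (int j = 0; j < n; ++j)
    if (pop[j] > 0) members[pop[j] - 1].push_back(j);

  bool any_scaling = false, any_event_rule = false;
  for (int i = 0; i < n_pops; ++i) {
    if (plast_on && rule[i] == 2) any_scaling = true;
    if (plast_on && (rule[i] == 1 || rule[i] == 3)) any_event_rule = true;
  }
  // affine accumulators for scaling populations: w_cur = A * w0 + B
  std::vector<double> scA(n_pops, 1.0), scB(n_pops, 0.0);

  Trace x_pre;
  x_pre.init(n, dt, tau_stdp);
  double x_post_val = 0.0;
  long x_post_last = 0;

  // --- recording ---------------------------------------------------------
  List record = args["record"];
  const long trace_stride = as<long>(record["trace_stride"]);
  const double snap_every = as<double>(record["weights_every"]);
  const long snap_steps = snap_every > 0 ? (long)std::llround(snap_every / dt) : 0;
  const bool rec_input = as<bool>(record["input_spikes"]);
  const bool do_corr = as<bool>(record["correlation"]);
  const double tau_Z = as<double>(record["tau_Z"]);
  const double tau_Y = as<double>(record["tau_Y"]);
  const long burn_steps = (long)std::llround(as<double>(record["burn_in"]) / dt);
  const double decZ = std::exp(-dt / tau_Z), decY = std::exp(-dt / tau_Y);

  std::vector<double> Z(n_groups, 0.0);
  double Y = 0.0;
  std::vector<double> sumZ(n_groups, 0.0), sumZ2(n_groups, 0.0),
      sumZY(n_groups, 0.0);
  double sumY = 0.0, sumY2 = 0.0;
  long n_corr = 0;

  std::vector<double> tr_t, tr_u, tr_ge, tr_gi;
  std::vector<double> snap_times;
  std::vector<std::vector<double>> snaps;
  std::vector<double> in_t;
  std::vector<int> in_id;

  // --- block machinery ---------------------------------------------------
  const long block_steps =
      (mode == "raster") ? n_steps : (long)std::llround(dT / dt);
  std::vector<double> excW(block_steps, 0.0);
  std::vector<double> zcnt((size_t)block_steps * n_groups, 0.0);
  std::vector<std::vector<int>> inh_ev(block_steps);
  std::vector<long> next_ok;
  std::vector<double> y;
  if (mode != "raster") {
    next_ok.assign(n, 0L);
    if (mode == "natural") {
      const double a = 1.0 - dT / tau_OU;
      const double sd0 = std::sqrt(1.0 / (1.0 - a * a));
      y.assign(n_groups, 0.0);
      for (int g = 0; g < n_groups; ++g) y[g] = sd0 * R::norm_rand();
    }
  }
  std::vector<double> pE(n_groups, 0.0);
  std::vector<std::vector<double>> pI(n_pops, std::vector<double>(n_groups, 0.0));

  // --- state -------------------------------------------------------------
  double u = u_rest, g_E = 0.0, g_I = 0.0;
  long refr = 0;
  std::vector<double> post_spikes;
  const long max_spikes = (long)(0.25 * duration) + 100;  // ~250 Hz guard

  long raster_pos = 0;
  const long n_raster = raster_step.size();

  auto cur_w = [&](int j) -> double {
    const int p1 = pop[j];
    if (p1 > 0 && plast_on && rule[p1 - 1] == 2)
      return scA[p1 - 1] * w[j] + scB[p1 - 1];
    return w[j];
  };
  auto materialise = [&]() {
    std::vector<double> out(w);
    for (int i = 0; i < n_pops; ++i)
      if (plast_on && rule[i] == 2)
        for (int j : members[i]) out[j] = scA[i] * w[j] + scB[i];
    return out;
  };

  for (long block_start = 0; block_start < n_steps; block_start += block_steps) {
    const long block_end = std::min(block_start + block_steps, n_steps);
    const long bs = block_end - block_start;
    // reset block buffers
    std::fill(excW.begin(), excW.begin() + bs, 0.0);
    std::fill(zcnt.begin(), zcnt.begin() + (size_t)bs * n_groups, 0.0);
    for (long s = 0; s < bs; ++s) inh_ev[s].clear();

    if (mode == "natural" || mode == "pulse") {
      // per-group per-population spike probabilities for this block
      const double t_block = block_start * dt;
      for (int g = 0; g < n_groups; ++g) {
        double rE, rI;
        if (mode == "natural") {
          y[g] = y[g] * (1.0 - dT / tau_OU) + R::norm_rand();
          const double yp = y[g] > 0 ? y[g] : 0.0;
          rE = nu_E0 * yp + nu_Ebg;
          rI = nu_I0 * yp + nu_Ibg;
        } else {
          const bool in_win = (g + 1 == pulse_group) && t_block >= pulse_onset &&
                              t_block < pulse_onset + pulse_dur;
          rE = nu_Ebg + (in_win ? pulse_ampE : 0.0);
          rI = nu_Ibg + (in_win ? pulse_ampI : 0.0);
        }
        pE[g] = rE * dt / 1000.0;
        if (pE[g] >= 1.0) stop("kernel: excitatory rate * dt >= 1");
        for (int i = 0; i < n_pops; ++i) {
          pI[i][g] = gains[i] * rI * dt / 1000.0;
          if (pI[i][g] >= 1.0) stop("kernel: inhibitory rate * dt >= 1");
        }
      }
      // geometric-jump spike generation per afferent
      for (int j = 0; j < n; ++j) {
        const int g = group[j] - 1;
        const double p = (pop[j] == 0) ? pE[g] : pI[pop[j] - 1][g];
        if (p <= 0.0) continue;
        const long nref = (pop[j] == 0) ? ref_steps_E : ref_steps_I;
        const double lq = std::log1p(-p);
        long cur = std::max(block_start, next_ok[j]);
        while (cur < block_end) {
          const double k = std::floor(std::log(safe_unif()) / lq);
          if (k > (double)(block_end - cur)) break;
          const long s = cur + (long)k;
          if (s >= block_end) break;
          const long sb = s - block_start;
          if (pop[j] == 0) {
            excW[sb] += w[j];
            zcnt[(size_t)sb * n_groups + g] += 1.0;
          } else {
            inh_ev[sb].push_back(j);
          }
          if (rec_input) {
            in_t.push_back((s + 1) * dt);
            in_id.push_back(j + 1);
          }
          next_ok[j] = s + nref + 1;
          cur = next_ok[j];
        }
      }
    }

    // ---- inner integration loop ----------------------------------------
    for (long s = block_start; s < block_end; ++s) {
      const long sb = s - block_start;
      g_E *= decE;
      g_I *= decI;
      bool have_inh = false;
      if (mode == "raster") {
        while (raster_pos < n_raster && raster_step[raster_pos] - 1 == s) {
          const int j = raster_id[raster_pos] - 1;
          if (pop[j] == 0) {
            g_E += w[j];
            if (do_corr)
              zcnt[(size_t)sb * n_groups + (group[j] - 1)] += 1.0;
          } else {
            g_I += cur_w(j);
            inh_ev[sb].push_back(j);
            have_inh = true;
          }
          ++raster_pos;
        }
      } else {
        g_E += excW[sb];
        if (!inh_ev[sb].empty()) {
          have_inh = true;
          for (int j : inh_ev[sb]) g_I += cur_w(j);
        }
      }

      bool spiked = false;
      if (refr > 0) {
        --refr;
        u = u_reset;
      } else {
        u += (dt / tau_m) *
             (-(u - u_rest) - g_E * (u - E_E) - g_I * (u - E_I));
        if (u >= u_th) {
          spiked = true;
          u = u_reset;
          refr = ref_steps;
          post_spikes.push_back((s + 1) * dt);
          if ((long)post_spikes.size() > max_spikes)
            stop("divergence: postsynaptic rate exceeded 250 Hz sustained");
        }
      }
      if (!std::isfinite(u) || !std::isfinite(g_E) || !std::isfinite(g_I)) {
        std::string bad = !std::isfinite(u) ? "membrane potential u"
                          : (!std::isfinite(g_E) ? "conductance g_E"
                                                 : "conductance g_I");
        stop("integration failure: non-finite " + bad + " at t = " +
             std::to_string((s + 1) * dt) + " ms");
      }

      // ---- plasticity (event rules read traces before this step's bumps)
      if (plast_on && any_event_rule && (spiked || have_inh)) {
        const double xp = x_post_val *
                          std::exp(-(double)(s - x_post_last) * dt / tau_stdp);
        const double t_now = (s + 1) * dt;
        const double eta_aH =
            t_now < t0_aH ? 0.0
                          : eta_aH0 * std::exp(-(t_now - t0_aH) / tau_aH);
        if (have_inh) {
          for (int j : inh_ev[sb]) {
            const int r = rule[pop[j] - 1];
            if (r == 1) {
              w[j] += eta_H * (xp - alpha_H);
              if (w[j] < 0) w[j] = 0;
            } else if (r == 3) {
              w[j] -= eta_aH * (xp - alpha_aH);
              if (w[j] < 0) w[j] = 0;
            }
          }
        }
        if (spiked) {
          for (int i = 0; i < n_pops; ++i) {
            if (rule[i] == 1) {
              for (int j : members[i]) w[j] += eta_H * x_pre.at(j, s);
            } else if (rule[i] == 3) {
              for (int j : members[i]) {
                w[j] -= eta_aH * x_pre.at(j, s);
                if (w[j] < 0) w[j] = 0;
              }
            }
          }
        }
        if (have_inh)
          for (int j : inh_ev[sb]) x_pre.bump(j, s);
        if (spiked) {
          x_post_val = xp + 1.0;
          x_post_last = s;
        }
      }
      if (any_scaling) {
        y_post = y_post * dec_sc + (spiked ? y_jump : 0.0);
        if (y_post > alpha_s * rho_0) {
          const double d = eta_s_eff * dt * w_Is * (y_post - rho_0);
          for (int i = 0; i < n_pops; ++i)
            if (rule[i] == 2) scB[i] += d;
        } else if (y_post < rho_0 / alpha_s) {
          const double c = 1.0 - eta_s_eff * dt * (rho_0 - y_post);
          for (int i = 0; i < n_pops; ++i)
            if (rule[i] == 2) {
              scA[i] *= c;
              scB[i] *= c;
            }
        }
      }

      // ---- correlation filters -------------------------------------------
      if (do_corr) {
        Y *= decY;
        if (spiked) Y += 1.0 / tau_Y;
        const double *zrow = &zcnt[(size_t)sb * n_groups];
        for (int g = 0; g < n_groups; ++g) {
          Z[g] *= decZ;
          if (zrow[g] > 0) Z[g] += zrow[g] / tau_Z;
        }
        if (s >= burn_steps) {
          ++n_corr;
          sumY += Y;
          sumY2 += Y * Y;
          for (int g = 0; g < n_groups; ++g) {
            sumZ[g] += Z[g];
            sumZ2[g] += Z[g] * Z[g];
            sumZY[g] += Z[g] * Y;
          }
        }
      }

      if (trace_stride > 0 && ((s + 1) % trace_stride == 0)) {
        tr_t.push_back((s + 1) * dt);
        tr_u.push_back(u);
        tr_ge.push_back(g_E);
        tr_gi.push_back(g_I);
      }
      if (snap_steps > 0 && ((s + 1) % snap_steps == 0)) {
        snap_times.push_back((s + 1) * dt);
        snaps.push_back(materialise());
      }
    }
    if (block_start / block_steps % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // --- outputs -----------------------------------------------------------
  std::vector<double> w_final = materialise();
  NumericVector C(n_groups, NA_REAL);
  if (do_corr && n_corr > 1) {
    const double varY = sumY2 / n_corr - (sumY / n_corr) * (sumY / n_corr);
    for (int g = 0; g < n_groups; ++g) {
      const double mZ = sumZ[g] / n_corr;
      const double varZ = sumZ2[g] / n_corr - mZ * mZ;
      const double cov = sumZY[g] / n_corr - mZ * (sumY / n_corr);
      if (varZ > 0 && varY > 0) C[g] = cov / std::sqrt(varZ * varY);
    }
  }

  List out = List::create(
      _["spikes"] = wrap(post_spikes), _["w_final"] = wrap(w_final),
      _["y_post"] = y_post, _["C"] = C, _["n_corr"] = (double)n_corr,
      _["duration"] = duration);
  if (trace_stride > 0)
    out["trace"] = DataFrame::create(_["t"] = wrap(tr_t), _["u"] = wrap(tr_u),
                                     _["g_E"] = wrap(tr_ge),
                                     _["g_I"] = wrap(tr_gi));
  if (snap_steps > 0) {
    NumericMatrix m(snaps.size(), n);
    for (size_t i = 0; i < snaps.size(); ++i)
      for (int j = 0; j < n; ++j) m(i, j) = snaps[i][j];
    out["w_snapshots"] = m;
    out["snapshot_times"] = wrap(snap_times);
  }
  if (rec_input)
    out["input_spikes"] =
        DataFrame::create(_["time"] = wrap(in_t), _["afferent"] = wrap(in_id));
  return out;
}
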