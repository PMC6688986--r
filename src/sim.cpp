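// Event-driven cores for the asynchronous teacher-student simulator.
//
// All randomness stays on the R side; every function here is deterministic
// given its arguments.  The present_* functions implement the per-example
// three-step protocol (output production -> adaptation -> learning) and are
// the hot path of run_learning_curve(); they MUTATE the weight/strength
// vectors passed in (the R wrappers copy first when functional semantics are
// wanted).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double clipv(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// STDP multiplicative factor (1 + delta(lag)); lag = t_stim - t_spike, so a
// positive lag (stimulation after the spike) strengthens.  kernel_exp = 0 is
// the step kernel delta = +-A, 1 is A * exp(-|lag|/tau_s) * sign(lag).
// sign(0) = 0: a coincident stimulation is left unchanged.
inline double stdp_fac(double lag, double A, int kernel_exp, double tau_s) {
  if (lag == 0.0) return 1.0;
  const double s = lag > 0.0 ? 1.0 : -1.0;
  const double d = kernel_exp ? A * std::exp(-std::fabs(lag) / tau_s) * s
                              : A * s;
  return 1.0 + d;
}

// Pairing factor for one sub-threshold event at time t against a sorted
// spike train.  pair_all = 0: nearest spike within the cutoff window, ties
// broken toward the earlier spike; pair_all = 1: one factor per spike within
// the cutoff, accumulated multiplicatively.
double pair_fac(double t, const std::vector<double>& spk,
                double A, int kernel_exp, double tau_s,
                double cutoff, int pair_all) {
  if (spk.empty()) return 1.0;
  if (pair_all) {
    double f = 1.0;
    for (double s : spk) {
      double lag = t - s;
      if (std::fabs(lag) <= cutoff) f *= stdp_fac(lag, A, kernel_exp, tau_s);
    }
    return f;
  }
  std::vector<double>::const_iterator it =
      std::lower_bound(spk.begin(), spk.end(), t);
  bool have = false;
  double best = 0.0;
  if (it != spk.begin()) { best = *(it - 1); have = true; }
  if (it != spk.end() &&
      (!have || std::fabs(*it - t) < std::fabs(t - best))) {
    best = *it;
  }
  double lag = t - best;
  if (std::fabs(lag) > cutoff) return 1.0;
  return stdp_fac(lag, A, kernel_exp, tau_s);
}

} // namespace

// Event-driven scaled LIF: exact exponential decay between delta inputs,
// threshold test at event instants only, reset to v_rest = 0 on spike.
// Returns per-event binary outputs and the peak voltage just after each
// drive is added (pre-reset), for oracle comparisons.
// [[Rcpp::export]]
List lif_run_cpp(NumericVector times, NumericVector drives,
                 double tau, double vth) {
  R_xlen_t n = times.size();
  IntegerVector out(n);
  NumericVector vpeak(n);
  double v = 0.0, tlast = 0.0;
  for (R_xlen_t k = 0; k < n; ++k) {
    v *= std::exp(-(times[k] - tlast) / tau);
    tlast = times[k];
    v += drives[k];
    vpeak[k] = v;
    if (v >= vth) { out[k] = 1; v = 0.0; } else { out[k] = 0; }
  }
  return List::create(_["output"] = out, _["v_peak"] = vpeak,
                      _["v_final"] = v);
}

// Per-dendrite LIF (one independent voltage per dendrite; a spike resets
// only its own dendrite).  dend is 0-based.
// [[Rcpp::export]]
List lif_run_dendritic_cpp(NumericVector times, NumericVector drives,
                           IntegerVector dend, int n_dendrites,
                           double tau, double vth) {
  R_xlen_t n = times.size();
  IntegerVector out(n);
  NumericVector vpeak(n);
  std::vector<double> v(n_dendrites, 0.0), tlast(n_dendrites, 0.0);
  for (R_xlen_t k = 0; k < n; ++k) {
    int d = dend[k];
    v[d] *= std::exp(-(times[k] - tlast[d]) / tau);
    tlast[d] = times[k];
    v[d] += drives[k];
    vpeak[k] = v[d];
    if (v[d] >= vth) { out[k] = 1; v[d] = 0.0; } else { out[k] = 0; }
  }
  return List::create(_["output"] = out, _["v_peak"] = vpeak);
}

// Brute-force fixed-step integrator of the same dynamics, used as an
// independent oracle.  Marches the membrane equation dV/dt = -V/tau on a
// regular grid of width dt with a 4th-order Taylor decay factor per step
// (plain Euler accumulates O(t*dt/tau^2) error, too coarse for a 1e-6
// voltage comparison); drives are injected at their nearest grid index.
// [[Rcpp::export]]
List lif_fixed_step_cpp(NumericVector times, NumericVector drives,
                        double dt, double tau, double vth) {
  R_xlen_t n = times.size();
  IntegerVector out(n);
  NumericVector vpeak(n);
  const double r = dt / tau;
  const double f = 1.0 - r + r * r / 2.0 - r * r * r / 6.0
                   + r * r * r * r / 24.0;
  double v = 0.0;
  long long step = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    long long target = (long long)std::llround(times[k] / dt);
    for (; step < target; ++step) v *= f;
    v += drives[k];
    vpeak[k] = v;
    if (v >= vth) { out[k] = 1; v = 0.0; } else { out[k] = 0; }
  }
  return List::create(_["output"] = out, _["v_peak"] = vpeak);
}

// One full example of the synaptic teacher-student protocol.
// units: 0-based stimulated unit per event; times sorted ascending.
// wT, wS are modified in place.  source_self = 1 makes the student adapt on
// its own trace instead of the teacher's.
// Returns outputs, mismatch count, attractive/repulsive step counts, and
// (optionally) the per-step records used for the Eq.-style attractive /
// repulsive bookkeeping: columns unit (1-based), teacher_before,
// student_before (both at the start of the example), student_pre,
// student_post (around the learning step).
// [[Rcpp::export]]
List present_synaptic_cpp(IntegerVector units, NumericVector times,
                          NumericVector amps,
                          NumericVector wT, NumericVector wS,
                          double tau, double vth,
                          double A, int kernel_exp, double tau_s,
                          double cutoff, int pair_all, int source_self,
                          double lambda, int learn_on,
                          double wlo, double whi,
                          int adapt_on, int record_steps) {
  R_xlen_t n = units.size();
  IntegerVector oT(n), oS(n);
  std::vector<double> wT0(n), wS0(n);
  std::vector<double> spkT, spkS;

  // 1) output production, teacher and student, with start-of-example weights
  {
    double v = 0.0, tlast = 0.0;
    for (R_xlen_t k = 0; k < n; ++k) {
      int u = units[k];
      wT0[k] = wT[u];
      v *= std::exp(-(times[k] - tlast) / tau);
      tlast = times[k];
      v += wT[u] * amps[k];
      if (v >= vth) { oT[k] = 1; v = 0.0; spkT.push_back(times[k]); }
    }
  }
  {
    double v = 0.0, tlast = 0.0;
    for (R_xlen_t k = 0; k < n; ++k) {
      int u = units[k];
      wS0[k] = wS[u];
      v *= std::exp(-(times[k] - tlast) / tau);
      tlast = times[k];
      v += wS[u] * amps[k];
      if (v >= vth) { oS[k] = 1; v = 0.0; spkS.push_back(times[k]); }
    }
  }

  // 2) adaptation: only sub-threshold events adapt; the teacher always
  // follows its own trace, the student follows the teacher's trace (default)
  // or its own (source_self).
  if (adapt_on) {
    for (R_xlen_t k = 0; k < n; ++k) {
      int u = units[k];
      if (oT[k] == 0) {
        double f = pair_fac(times[k], spkT, A, kernel_exp, tau_s,
                            cutoff, pair_all);
        wT[u] = clipv(wT[u] * f, wlo, whi);
        if (!source_self) wS[u] = clipv(wS[u] * f, wlo, whi);
      }
      if (source_self && oS[k] == 0) {
        double f = pair_fac(times[k], spkS, A, kernel_exp, tau_s,
                            cutoff, pair_all);
        wS[u] = clipv(wS[u] * f, wlo, whi);
      }
    }
  }

  // 3) learning on mismatch events, sequential in event-time order
  int mism = 0, n_att = 0, n_rep = 0, n_neu = 0;
  std::vector<double> rec;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (oT[k] == oS[k]) continue;
    ++mism;
    if (!learn_on || lambda == 0.0) continue;
    int u = units[k];
    double pre = wS[u];
    wS[u] = clipv(pre + lambda * (double)(oT[k] - oS[k]) * amps[k], wlo, whi);
    double prod = (wT0[k] - wS0[k]) * (wS[u] - pre);
    if (prod > 0.0) ++n_att; else if (prod < 0.0) ++n_rep; else ++n_neu;
    if (record_steps) {
      rec.push_back((double)(u + 1));
      rec.push_back(wT0[k]);
      rec.push_back(wS0[k]);
      rec.push_back(pre);
      rec.push_back(wS[u]);
    }
  }

  List res = List::create(
      _["o_teacher"] = oT, _["o_student"] = oS, _["mismatch"] = mism,
      _["n_attractive"] = n_att, _["n_repulsive"] = n_rep,
      _["n_neutral"] = n_neu);
  if (record_steps) {
    R_xlen_t m = (R_xlen_t)rec.size() / 5;
    NumericMatrix sm(m, 5);
    for (R_xlen_t i = 0; i < m; ++i)
      for (int j = 0; j < 5; ++j) sm(i, j) = rec[i * 5 + j];
    colnames(sm) = CharacterVector::create(
        "unit", "teacher_before", "student_before", "student_pre",
        "student_post");
    res["steps"] = sm;
  }
  return res;
}

// One full example of the dendritic teacher-student protocol.
// dend: 0-based dendrite per event; rankv: stimulation rank of the event's
// dendrite within this example (block rank for primary events, fractional
// for weak-fill events).  Drives are J[d] * w_fixed[unit] * amplitude; each
// dendrite integrates only its own events.  JT, JS modified in place.
// rank_mode = 1: reference spikes are those of *other* dendrites whose rank
// lies within +-rank_window, no time cutoff, one factor per spike;
// rank_mode = 0: time-window pairing as in the synaptic case but restricted
// to spikes of other dendrites.  Adaptation factors accumulate over the
// example and J is clipped once at the end.
// [[Rcpp::export]]
List present_dendritic_cpp(IntegerVector units, NumericVector times,
                           NumericVector amps, IntegerVector dend,
                           NumericVector rankv,
                           NumericVector w_fixed,
                           NumericVector JT, NumericVector JS,
                           double tau, double vth,
                           double A, int kernel_exp, double tau_s,
                           double cutoff, int rank_mode, double rank_window,
                           int pair_all, int source_self,
                           double lambda, int learn_on,
                           double jlo, double jhi,
                           int adapt_on, int record_steps) {
  R_xlen_t n = units.size();
  int K = JT.size();
  IntegerVector oT(n), oS(n);
  std::vector<double> JT0(JT.begin(), JT.end());
  std::vector<double> JS0(JS.begin(), JS.end());

  // 1) output production
  {
    std::vector<double> v(K, 0.0), tl(K, 0.0);
    for (R_xlen_t k = 0; k < n; ++k) {
      int d = dend[k];
      v[d] *= std::exp(-(times[k] - tl[d]) / tau);
      tl[d] = times[k];
      v[d] += JT[d] * w_fixed[units[k]] * amps[k];
      if (v[d] >= vth) { oT[k] = 1; v[d] = 0.0; }
    }
  }
  {
    std::vector<double> v(K, 0.0), tl(K, 0.0);
    for (R_xlen_t k = 0; k < n; ++k) {
      int d = dend[k];
      v[d] *= std::exp(-(times[k] - tl[d]) / tau);
      tl[d] = times[k];
      v[d] += JS[d] * w_fixed[units[k]] * amps[k];
      if (v[d] >= vth) { oS[k] = 1; v[d] = 0.0; }
    }
  }

  // 2) adaptation: per-dendrite multiplicative factor accumulated over the
  // example from the reference trace, then applied and clipped once.
  if (adapt_on) {
    // reference spike lists with dendrite ids and ranks
    std::vector<double> facT(K, 1.0), facS(K, 1.0);

    // factors driven by a given trace
    const IntegerVector* oref[2] = { &oT, &oS };
    for (int which = 0; which < (source_self ? 2 : 1); ++which) {
      const IntegerVector& o = *oref[which];
      std::vector<double> spk_t;
      std::vector<int> spk_d;
      std::vector<double> spk_r;
      std::vector<double> spk_sorted;
      for (R_xlen_t k = 0; k < n; ++k) {
        if (o[k]) {
          spk_t.push_back(times[k]);
          spk_d.push_back(dend[k]);
          spk_r.push_back(rankv[k]);
          spk_sorted.push_back(times[k]);
        }
      }
      std::vector<double>& fac = (which == 0) ? facT : facS;
      for (R_xlen_t k = 0; k < n; ++k) {
        if (o[k]) continue;
        int d = dend[k];
        if (rank_mode) {
          // sign by stimulation-rank order (a spike from a prior-ranked
          // dendrite strengthens), keeping the number and strength of
          // steps symmetric on both sides of a spiking dendrite; the
          // exponential kernel still draws its magnitude from the lag
          for (size_t s = 0; s < spk_t.size(); ++s) {
            if (spk_d[s] == d) continue;
            if (std::fabs(spk_r[s] - rankv[k]) > rank_window) continue;
            double sgn = rankv[k] > spk_r[s] ? 1.0 :
                         (rankv[k] < spk_r[s] ? -1.0 : 0.0);
            double mag = kernel_exp
              ? A * std::exp(-std::fabs(times[k] - spk_t[s]) / tau_s) : A;
            fac[d] *= 1.0 + sgn * mag;
          }
        } else {
          // nearest spike of another dendrite within the time cutoff
          std::vector<double> others;
          others.reserve(spk_t.size());
          for (size_t s = 0; s < spk_t.size(); ++s)
            if (spk_d[s] != d) others.push_back(spk_t[s]);
          fac[d] *= pair_fac(times[k], others, A, kernel_exp, tau_s,
                             cutoff, pair_all);
        }
      }
    }

    for (int d = 0; d < K; ++d) {
      JT[d] = clipv(JT[d] * facT[d], jlo, jhi);
      JS[d] = clipv(JS[d] * (source_self ? facS[d] : facT[d]), jlo, jhi);
    }
  }

  // 3) learning on mismatch events (student only), sequential in time
  int mism = 0, n_att = 0, n_rep = 0, n_neu = 0;
  std::vector<double> rec;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (oT[k] == oS[k]) continue;
    ++mism;
    if (!learn_on || lambda == 0.0) continue;
    int d = dend[k];
    double pre = JS[d];
    JS[d] = clipv(pre + lambda * (double)(oT[k] - oS[k]) * amps[k], jlo, jhi);
    double prod = (JT0[d] - JS0[d]) * (JS[d] - pre);
    if (prod > 0.0) ++n_att; else if (prod < 0.0) ++n_rep; else ++n_neu;
    if (record_steps) {
      rec.push_back((double)(d + 1));
      rec.push_back(JT0[d]);
      rec.push_back(JS0[d]);
      rec.push_back(pre);
      rec.push_back(JS[d]);
    }
  }

  List res = List::create(
      _["o_teacher"] = oT, _["o_student"] = oS, _["mismatch"] = mism,
      _["n_attractive"] = n_att, _["n_repulsive"] = n_rep,
      _["n_neutral"] = n_neu);
  if (record_steps) {
    R_xlen_t m = (R_xlen_t)rec.size() / 5;
    NumericMatrix sm(m, 5);
    for (R_xlen_t i = 0; i < m; ++i)
      for (int j = 0; j < 5; ++j) sm(i, j) = rec[i * 5 + j];
    colnames(sm) = CharacterVector::create(
        "dendrite", "teacher_before", "student_before", "student_pre",
        "student_post");
    res["steps"] = sm;
  }
  return res;
}

// Mismatch count between two frozen synaptic networks on one example.
// [[Rcpp::export]]
int eval_synaptic_cpp(IntegerVector units, NumericVector times,
                      NumericVector amps, NumericVector wT, NumericVector wS,
                      double tau, double vth) {
  R_xlen_t n = units.size();
  double vT = 0.0, vS = 0.0, tlT = 0.0, tlS = 0.0;
  int mism = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    int u = units[k];
    double dt = times[k];
    vT *= std::exp(-(dt - tlT) / tau); tlT = dt;
    vS *= std::exp(-(dt - tlS) / tau); tlS = dt;
    vT += wT[u] * amps[k];
    vS += wS[u] * amps[k];
    int bT = vT >= vth, bS = vS >= vth;
    if (bT) vT = 0.0;
    if (bS) vS = 0.0;
    if (bT != bS) ++mism;
  }
  return mism;
}

// Mismatch count between two frozen dendritic networks on one example.
// [[Rcpp::export]]
int eval_dendritic_cpp(IntegerVector units, NumericVector times,
                       NumericVector amps, IntegerVector dend,
                       NumericVector w_fixed,
                       NumericVector JT, NumericVector JS,
                       double tau, double vth) {
  R_xlen_t n = units.size();
  int K = JT.size();
  std::vector<double> vT(K, 0.0), vS(K, 0.0), tlT(K, 0.0), tlS(K, 0.0);
  int mism = 0;
  for (R_xlen_t k = 0; k < n; ++k) {
    int d = dend[k];
    double w = w_fixed[units[k]] * amps[k];
    vT[d] *= std::exp(-(times[k] - tlT[d]) / tau); tlT[d] = times[k];
    vS[d] *= std::exp(-(times[k] - tlS[d]) / tau); tlS[d] = times[k];
    vT[d] += JT[d] * w;
    vS[d] += JS[d] * w;
    int bT = vT[d] >= vth, bS = vS[d] >= vth;
    if (bT) vT[d] = 0.0;
    if (bS) vS[d] = 0.0;
    if (bT != bS) ++mism;
  }
  return mism;
}
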