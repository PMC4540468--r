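// Discrete-time core of the spiking-sheet sampler.
//
// One call advances the network by n_steps of size dt.  Within a step:
//   (1) all inputs update (Poisson-like spike draws against the current
//       piecewise-constant target activations, rectangular PSPs of
//       tau_steps), then
//   (2) network neurons are visited in a fresh uniformly random order; a
//       neuron is eligible iff its state variable is 0 or in its last
//       active step, and spikes with probability sigma(u - log tau_steps),
//       state transitions being visible to later-visited neurons, then
//   (3) optional Euler plasticity updates are applied on the step's states.
//
// Randomness comes from a self-contained PCG32 stream seeded from R, so a
// run is reproducible bit-for-bit.  Consumption order per step: inputs by
// index, the visit-order shuffle, spike draws of eligible neurons in visit
// order, then (wake-sleep only) the companion prior sampler's shuffle and
// draws.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>

static const double HALF_PI = std::acos(0.0);

using namespace Rcpp;

namespace {

struct Pcg32 {
  uint64_t state, inc;
  explicit Pcg32(uint64_t seed) {
    // splitmix64 expansion of a small seed into state/stream constants
    uint64_t z = seed;
    auto mix = [&z]() {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      return t ^ (t >> 31);
    };
    state = mix();
    inc = mix() | 1ULL;
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() {  // uniform in (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
  int below(int n) {  // uniform integer in [0, n)
    return (int)(runif() * n) % n;
  }
};

inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

}  // namespace

// Enumerate all binary states z in {0,1}^K with no pair (k,j),
// mask[k,j] = TRUE, simultaneously active.  Lexicographic order in
// (z_1, ..., z_K): depth-first, trying z_k = 0 before z_k = 1.
// [[Rcpp::export(name = ".cpp_valid_states")]]
IntegerMatrix cpp_valid_states(LogicalMatrix mask) {
  int K = mask.nrow();
  std::vector<std::vector<int>> nbr(K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j)
      if (mask(k, j) && j != k) nbr[k].push_back(j);
  std::vector<int> z(K, 0);
  std::vector<std::vector<int>> out;
  // iterative DFS over positions
  std::function<void(int)> rec = [&](int k) {
    if (k == K) { out.push_back(z); return; }
    z[k] = 0;
    rec(k + 1);
    bool ok = true;
    for (int j : nbr[k])
      if (j < k && z[j]) { ok = false; break; }
    if (ok) {
      z[k] = 1;
      rec(k + 1);
      z[k] = 0;
    }
  };
  rec(0);
  IntegerMatrix m((int)out.size(), K);
  for (int s = 0; s < (int)out.size(); ++s)
    for (int k = 0; k < K; ++k) m(s, k) = out[s][k];
  return m;
}

// Count valid states without materializing them (used for large K).
// [[Rcpp::export(name = ".cpp_count_valid_states")]]
double cpp_count_valid_states(LogicalMatrix mask) {
  int K = mask.nrow();
  std::vector<std::vector<int>> nbr(K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j)
      if (mask(k, j) && j != k) nbr[k].push_back(j);
  std::vector<int> z(K, 0);
  double count = 0;
  std::function<void(int)> rec = [&](int k) {
    if (k == K) { count += 1; return; }
    z[k] = 0;
    rec(k + 1);
    bool ok = true;
    for (int j : nbr[k])
      if (j < k && z[j]) { ok = false; break; }
    if (ok) {
      z[k] = 1;
      rec(k + 1);
      z[k] = 0;
    }
  };
  rec(0);
  return count;
}

// Full simulation run.  All matrices are modified on copies and returned.
//
// field_idx / field_ptr : CSR layout of afferent fields I_k (0-based input
//   indices; field_ptr has length K+1).
// proj_idx / proj_ptr : CSR layout of projection fields P_i (neurons per
//   input), used to maintain the afferent drive incrementally.
// nbr_idx / nbr_ptr : CSR layout of recurrent neighbours (union of the
//   excitatory support and nonzero inhibitory weights).
// exc_i / exc_j : unordered excitatory pairs (i < j, 0-based) subject to
//   recurrent plasticity.
// seg_steps / X : piecewise-constant input schedule (duration in steps of
//   each segment; one row of target activations per segment).  Ignored if
//   y_given has rows.
// rule : 0 = none, 1 = wake-sleep, 2 = heuristic.
//
// Input spikes are drawn by geometric skip-ahead (one draw per spike, not
// per step), which realizes the same per-step Bernoulli(p_i) process.
// Synaptic plasticity (V, Wexc and the companion biases) is accumulated
// over batches of tau_steps steps and flushed as one Euler update with the
// batch's summed pre/post coincidence counts; the slow terms (sigmoid of
// V, LTD of Wexc) are evaluated once per flush.  Homeostatic updates of b
// are applied every step.
// [[Rcpp::export(name = ".cpp_run_sheet")]]
List cpp_run_sheet(int n_steps, int tau_steps, double dt,
                   NumericMatrix V_in, NumericVector V0, NumericVector b_in,
                   NumericMatrix Wexc_in, NumericMatrix Winh,
                   IntegerVector field_idx, IntegerVector field_ptr,
                   IntegerVector proj_idx, IntegerVector proj_ptr,
                   IntegerVector nbr_idx, IntegerVector nbr_ptr,
                   IntegerVector exc_i, IntegerVector exc_j,
                   IntegerVector seg_steps, NumericMatrix X,
                   IntegerMatrix y_given,
                   IntegerVector z_cd_in, IntegerVector y_cd_in,
                   IntegerVector s_cd_in, NumericVector bsleep_in,
                   bool plastic, double eta_v, double eta_b, double eta_w,
                   NumericVector m, int rule, double wmax, double gamma,
                   bool nonneg, double eta_b_sleep,
                   bool rec_z, bool rec_y, bool rec_spikes, bool rec_occ,
                   bool rec_coact, int occ_burn_in,
                   int stat_start, int wavg_start, int batch_steps,
                   double seed) {
  int K = V_in.nrow(), N = V_in.ncol();
  NumericMatrix V = clone(V_in), Wexc = clone(Wexc_in);
  NumericVector b = clone(b_in), bsleep = clone(bsleep_in);
  IntegerVector z_cd = clone(z_cd_in), y_cd = clone(y_cd_in),
                s_cd = clone(s_cd_in);

  Pcg32 rng((uint64_t)seed);
  const double log_tau = std::log((double)tau_steps);
  const bool use_given = y_given.nrow() > 0;
  const double w_eps = 1e-6 * (wmax > 0 ? wmax : 1.0);
  const int n_exc = exc_i.size();
  const int n_field = field_idx.size();

  // schedule bookkeeping + geometric skip-ahead spike clocks
  int seg = 0, seg_left = 0;
  std::vector<double> log1mp(N, 0.0);
  std::vector<int> gap(N, INT32_MAX);
  auto draw_gap = [&](int i) {
    if (log1mp[i] >= 0) { gap[i] = INT32_MAX; return; }
    double g = std::floor(std::log(rng.runif()) / log1mp[i]);
    gap[i] = (g > 2e9) ? INT32_MAX : (int)g + 1;
  };
  auto enter_segment = [&](int s) {
    for (int i = 0; i < N; ++i) {
      double x = X(s, i);
      double p = (x <= 0) ? 0.0 : 1.0 - std::pow(1.0 - x, 1.0 / tau_steps);
      log1mp[i] = (p <= 0) ? 0.0 : std::log1p(-p);
      draw_gap(i);
    }
  };
  if (!use_given && X.nrow() > 0) {
    enter_segment(0);
    seg_left = seg_steps[0];
  }

  std::vector<int> z(K), y(N), zs(K), order(K);
  for (int k = 0; k < K; ++k) z[k] = z_cd[k] > 0;
  for (int k = 0; k < K; ++k) zs[k] = s_cd[k] > 0;
  for (int i = 0; i < N; ++i) y[i] = y_cd[i] > 0;

  // afferent drive a_k = sum_{i in I_k, y_i = 1} V_ki, kept incrementally
  std::vector<double> adrive(K, 0.0);
  // column position of input i within row k's field (for V lookups from
  // the projection side we just use the dense matrix directly)
  auto recompute_drive = [&]() {
    for (int k = 0; k < K; ++k) {
      double a = 0;
      for (int q = field_ptr[k]; q < field_ptr[k + 1]; ++q)
        if (y[field_idx[q]]) a += V(k, field_idx[q]);
      adrive[k] = a;
    }
  };
  recompute_drive();

  // plasticity accumulators (flushed every tau_steps steps)
  std::vector<double> czy(plastic && eta_v > 0 ? n_field : 0, 0.0);
  std::vector<double> cz(K, 0.0), czsleep(K, 0.0);
  std::vector<double> czz(plastic && eta_w > 0 && rule != 0 ? n_exc : 0,
                          0.0);
  std::vector<double> czz_sleep(rule == 1 ? n_exc : 0, 0.0);
  int batch_n = 0;
  if (batch_steps < 1) batch_steps = 1;
  // dense pair-index lookup so coincidence counting can iterate over the
  // (few) active neurons instead of all excitatory pairs
  std::vector<int> exc_index((size_t)K * K, -1);
  for (int p = 0; p < n_exc; ++p) {
    exc_index[(size_t)exc_i[p] * K + exc_j[p]] = p;
    exc_index[(size_t)exc_j[p] * K + exc_i[p]] = p;
  }
  auto flush_plasticity = [&]() {
    if (!plastic || batch_n == 0) return;
    if (eta_v > 0) {
      for (int k = 0; k < K; ++k) {
        if (cz[k] == 0) continue;
        for (int q = field_ptr[k]; q < field_ptr[k + 1]; ++q) {
          int i = field_idx[q];
          double dv = dt * eta_v *
                      (czy[q] - cz[k] * sigmoid(V(k, i) + V0[i]));
          double nv = V(k, i) + dv;
          if (nonneg && nv < 0) nv = 0;
          if (y[i]) adrive[k] += nv - V(k, i);
          V(k, i) = nv;
        }
      }
      std::fill(czy.begin(), czy.end(), 0.0);
    }
    if (eta_w > 0 && rule != 0) {
      for (int p = 0; p < n_exc; ++p) {
        int k = exc_i[p], j = exc_j[p];
        double dw;
        if (rule == 1) {
          dw = dt * eta_w * (czz[p] - czz_sleep[p]);
        } else {
          double w = Wexc(k, j);
          double ltd = m[k] * m[j] + std::tan(HALF_PI * w / wmax) / gamma;
          dw = dt * eta_w * (czz[p] - batch_n * ltd);
        }
        double nw = Wexc(k, j) + dw;
        if (nonneg && nw < 0) nw = 0;
        if (rule == 2 && nw > wmax - w_eps) nw = wmax - w_eps;
        Wexc(k, j) = nw;
        Wexc(j, k) = nw;
      }
      std::fill(czz.begin(), czz.end(), 0.0);
      if (rule == 1) {
        std::fill(czz_sleep.begin(), czz_sleep.end(), 0.0);
        if (eta_b_sleep > 0)
          for (int k = 0; k < K; ++k)
            bsleep[k] += dt * eta_b_sleep * (cz[k] - czsleep[k]);
        std::fill(czsleep.begin(), czsleep.end(), 0.0);
      }
    }
    std::fill(cz.begin(), cz.end(), 0.0);
    batch_n = 0;
  };

  // recordings
  IntegerMatrix zmat(rec_z ? n_steps : 0, rec_z ? K : 0);
  IntegerMatrix ymat(rec_y ? n_steps : 0, rec_y ? N : 0);
  std::vector<int> sp_step, sp_id, sp_pop;
  std::unordered_map<uint32_t, double> occ;
  NumericVector zsum(K), spike_count(K);
  NumericMatrix coact(rec_coact ? K : 0, rec_coact ? K : 0);
  NumericMatrix wsum(K, K);
  double wsum_n = 0;
  long stat_n = 0;
  std::vector<int> active;
  active.reserve(K);

  for (int t = 0; t < n_steps; ++t) {
    // ---- inputs -----------------------------------------------------
    if (use_given) {
      for (int i = 0; i < N; ++i) {
        int yi = y_given(t, i);
        if (yi != y[i]) {
          if (rec_spikes && yi) {
            sp_step.push_back(t); sp_id.push_back(i); sp_pop.push_back(1);
          }
          double sgn = yi ? 1.0 : -1.0;
          for (int q = proj_ptr[i]; q < proj_ptr[i + 1]; ++q)
            adrive[proj_idx[q]] += sgn * V(proj_idx[q], i);
          y[i] = yi;
        }
      }
    } else {
      for (int i = 0; i < N; ++i) {
        if (--gap[i] == 0) {
          if (rec_spikes) {
            sp_step.push_back(t); sp_id.push_back(i); sp_pop.push_back(1);
          }
          y_cd[i] = tau_steps;
          draw_gap(i);
          if (!y[i]) {
            for (int q = proj_ptr[i]; q < proj_ptr[i + 1]; ++q)
              adrive[proj_idx[q]] += V(proj_idx[q], i);
            y[i] = 1;
          }
        } else if (y_cd[i] > 0) {
          if (--y_cd[i] == 0) {
            for (int q = proj_ptr[i]; q < proj_ptr[i + 1]; ++q)
              adrive[proj_idx[q]] -= V(proj_idx[q], i);
            y[i] = 0;
          }
        }
      }
      // advance the schedule *after* consuming this step's segment
      if (seg_left > 0) --seg_left;
      if (seg_left == 0 && seg + 1 < X.nrow()) {
        ++seg;
        enter_segment(seg);
        seg_left = seg_steps[seg];
      }
    }

    // ---- network neurons, random sequential order -------------------
    for (int k = 0; k < K; ++k) order[k] = k;
    for (int k = K - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(order[k], order[j]);
    }
    for (int v = 0; v < K; ++v) {
      int k = order[v];
      if (z_cd[k] > 1) {  // refractory, stays active
        --z_cd[k];
        continue;
      }
      double u = b[k] + adrive[k];
      for (int q = nbr_ptr[k]; q < nbr_ptr[k + 1]; ++q) {
        int j = nbr_idx[q];
        if (z[j]) u += Wexc(k, j) + Winh(k, j);
      }
      double pr = sigmoid(u - log_tau);
      if (rng.runif() < pr) {
        if (rec_spikes) {
          sp_step.push_back(t); sp_id.push_back(k); sp_pop.push_back(0);
        }
        if (t >= stat_start) spike_count[k] += 1;
        z_cd[k] = tau_steps;
        z[k] = 1;
      } else {
        z_cd[k] = 0;
        z[k] = 0;
      }
    }

    // ---- companion prior sampler (wake-sleep only) -------------------
    if (plastic && rule == 1) {
      for (int k = 0; k < K; ++k) order[k] = k;
      for (int k = K - 1; k > 0; --k) {
        int j = rng.below(k + 1);
        std::swap(order[k], order[j]);
      }
      for (int v = 0; v < K; ++v) {
        int k = order[v];
        if (s_cd[k] > 1) { --s_cd[k]; continue; }
        double u = bsleep[k];
        for (int q = nbr_ptr[k]; q < nbr_ptr[k + 1]; ++q) {
          int j = nbr_idx[q];
          if (zs[j]) u += Wexc(k, j) + Winh(k, j);
        }
        double pr = sigmoid(u - log_tau);
        if (rng.runif() < pr) { s_cd[k] = tau_steps; zs[k] = 1; }
        else { s_cd[k] = 0; zs[k] = 0; }
      }
    }

    // ---- plasticity accumulation -------------------------------------
    if (plastic) {
      active.clear();
      for (int k = 0; k < K; ++k) if (z[k]) active.push_back(k);
      if (eta_b > 0)
        for (int k = 0; k < K; ++k) b[k] += dt * eta_b * (m[k] - z[k]);
      for (int k : active) cz[k] += 1;
      if (eta_v > 0) {
        for (int k : active)
          for (int q = field_ptr[k]; q < field_ptr[k + 1]; ++q)
            czy[q] += y[field_idx[q]];
      }
      if (eta_w > 0 && rule != 0) {
        for (size_t a = 0; a < active.size(); ++a)
          for (size_t bb = a + 1; bb < active.size(); ++bb) {
            int p = exc_index[(size_t)active[a] * K + active[bb]];
            if (p >= 0) czz[p] += 1;
          }
        if (rule == 1) {
          for (int k = 0; k < K; ++k)
            if (zs[k]) {
              czsleep[k] += 1;
              for (int j = k + 1; j < K; ++j)
                if (zs[j]) {
                  int p = exc_index[(size_t)k * K + j];
                  if (p >= 0) czz_sleep[p] += 1;
                }
            }
        }
      }
      ++batch_n;
      if (batch_n >= batch_steps) flush_plasticity();
    }

    // ---- recording ----------------------------------------------------
    if (rec_z) for (int k = 0; k < K; ++k) zmat(t, k) = z[k];
    if (rec_y) for (int i = 0; i < N; ++i) ymat(t, i) = y[i];
    if (rec_occ && t >= occ_burn_in) {
      uint32_t code = 0;
      for (int k = 0; k < K; ++k) if (z[k]) code |= (1u << k);
      occ[code] += 1;
    }
    if (t >= stat_start) {
      ++stat_n;
      for (int k = 0; k < K; ++k) zsum[k] += z[k];
      if (rec_coact) {
        for (int k = 0; k < K; ++k) {
          if (!z[k]) continue;
          for (int j = k; j < K; ++j)
            if (z[j]) { coact(k, j) += 1; if (j != k) coact(j, k) += 1; }
        }
      }
    }
    if (wavg_start >= 0 && t >= wavg_start) {
      wsum_n += 1;
      for (int p = 0; p < n_exc; ++p) {
        int k = exc_i[p], j = exc_j[p];
        wsum(k, j) += Wexc(k, j);
        wsum(j, k) += Wexc(k, j);
      }
    }
    if ((t & 0xFFFF) == 0xFFFF) recompute_drive();  // cap FP drift
  }
  flush_plasticity();

  // package occupancy
  int n_occ = (int)occ.size();
  NumericVector occ_code(n_occ), occ_count(n_occ);
  int idx = 0;
  for (auto &kv : occ) {
    occ_code[idx] = kv.first;
    occ_count[idx] = kv.second;
    ++idx;
  }

  return List::create(
      _["V"] = V, _["b"] = b, _["Wexc"] = Wexc, _["bsleep"] = bsleep,
      _["z_countdown"] = z_cd, _["y_countdown"] = y_cd,
      _["sleep_countdown"] = s_cd,
      _["zmat"] = zmat, _["ymat"] = ymat,
      _["spike_step"] = wrap(sp_step), _["spike_id"] = wrap(sp_id),
      _["spike_pop"] = wrap(sp_pop),
      _["occ_code"] = occ_code, _["occ_count"] = occ_count,
      _["zsum"] = zsum, _["spike_count"] = spike_count,
      _["coact"] = coact, _["stat_n"] = (double)stat_n,
      _["wavg"] = wsum, _["wavg_n"] = wsum_n);
}
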