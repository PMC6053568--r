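#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact stochastic simulation (direct method) of the patch model.
//
// Eight event channels per patch, in this fixed order:
//   0 herbivore birth            g_H * H
//   1 herbivore crowding death   g_H * H^2 / k_H
//   2 herbivore background death m_H * H
//   3 predation                  e_P * H / (H + H_0) * P
//   4 predator birth             a_P * e_P * H / (H + H_0) * P   (scenario ii)
//   5 predator background death  m_P * P                          (scenario ii)
//   6 herbivore emigration       d_H(H) * H
//   7 predator emigration        d_P(H) * P
//
// Deterministic timed points (state recording, interventions) are merged
// into the event loop by truncating the exponential waiting time at the
// next scheduled time; valid by memorylessness of the exponential.

namespace {

struct Pars {
  double g_H, k_H, e_P, H_0, a_P, m_H, m_P;
  double d_H_max, tau_H, s_H, d_P_max, tau_P, s_P;
  bool pred_demog;
  double pop_cap;
};

inline void patch_rates(const Pars& p, int H, int P, double* r) {
  double fr = p.e_P * H / (H + p.H_0);  // H_0 > 0 so safe at H = 0
  r[0] = p.g_H * H;
  r[1] = p.g_H * (double)H * H / p.k_H;
  r[2] = p.m_H * H;
  r[3] = fr * P;
  r[4] = p.pred_demog ? p.a_P * fr * P : 0.0;
  r[5] = p.pred_demog ? p.m_P * P : 0.0;
  r[6] = p.d_H_max / (1.0 + std::exp(-p.s_H * (H - p.tau_H))) * H;
  r[7] = p.d_P_max / (1.0 + std::exp(p.s_P * (H - p.tau_P))) * P;
}

inline double patch_total(const Pars& p, int H, int P) {
  double r[8];
  patch_rates(p, H, P, r);
  double s = 0.0;
  for (int k = 0; k < 8; ++k) s += r[k];
  return s;
}

}  // namespace

// [[Rcpp::export]]
List ssa_run_cpp(IntegerVector H_init, IntegerVector P_init, List pars,
                 NumericMatrix settle, NumericVector record_times,
                 NumericVector iv_time, IntegerVector iv_patch,
                 IntegerVector iv_species, IntegerVector iv_action,
                 IntegerVector iv_amount, double t_end, bool log_events) {
  const int N = H_init.size();
  Pars p;
  p.g_H = as<double>(pars["g_H"]);
  p.k_H = as<double>(pars["k_H"]);
  p.e_P = as<double>(pars["e_P"]);
  p.H_0 = as<double>(pars["H_0"]);
  p.a_P = as<double>(pars["a_P"]);
  p.m_H = as<double>(pars["m_H"]);
  p.m_P = as<double>(pars["m_P"]);
  p.d_H_max = as<double>(pars["d_H_max"]);
  p.tau_H = as<double>(pars["tau_H"]);
  p.s_H = as<double>(pars["s_H"]);
  p.d_P_max = as<double>(pars["d_P_max"]);
  p.tau_P = as<double>(pars["tau_P"]);
  p.s_P = as<double>(pars["s_P"]);
  p.pred_demog = as<bool>(pars["pred_demog"]);
  p.pop_cap = as<double>(pars["pop_cap"]);

  std::vector<int> H(H_init.begin(), H_init.end());
  std::vector<int> P(P_init.begin(), P_init.end());
  long total_pop = 0;
  for (int i = 0; i < N; ++i) {
    if (H[i] < 0 || P[i] < 0) stop("initial abundances must be non-negative");
    total_pop += H[i] + P[i];
  }

  // merged schedule: interventions first at ties, then recordings
  const int n_rec = record_times.size();
  const int n_iv = iv_time.size();
  struct Sched { double t; int kind; int idx; };  // kind 0 = iv, 1 = record
  std::vector<Sched> sched;
  sched.reserve(n_rec + n_iv);
  for (int k = 0; k < n_iv; ++k) sched.push_back({iv_time[k], 0, k});
  for (int k = 0; k < n_rec; ++k) sched.push_back({record_times[k], 1, k});
  std::stable_sort(sched.begin(), sched.end(),
                   [](const Sched& a, const Sched& b) {
                     if (a.t != b.t) return a.t < b.t;
                     return a.kind < b.kind;
                   });

  IntegerMatrix H_rec(N, n_rec), P_rec(N, n_rec);
  NumericVector ev_counts(8);
  double outside_H = 0.0, outside_P = 0.0;

  std::vector<double> tot(N);
  double S = 0.0;
  for (int i = 0; i < N; ++i) {
    tot[i] = patch_total(p, H[i], P[i]);
    S += tot[i];
  }

  double t = 0.0;
  std::size_t s_ptr = 0;
  long steps_since_refresh = 0;
  double r8[8];

  auto refresh_S = [&]() {
    S = 0.0;
    for (int i = 0; i < N; ++i) S += tot[i];
  };

  while (true) {
    double t_next_sched = (s_ptr < sched.size()) ? sched[s_ptr].t : t_end;
    double dt = (S > 0.0) ? -std::log(unif_rand()) / S
                          : R_PosInf;
    if (t + dt >= t_next_sched) {
      // advance to the scheduled point, apply everything due there
      t = t_next_sched;
      if (s_ptr >= sched.size() && t >= t_end) break;
      while (s_ptr < sched.size() && sched[s_ptr].t <= t) {
        const Sched& s = sched[s_ptr];
        if (s.kind == 1) {
          for (int i = 0; i < N; ++i) {
            H_rec(i, s.idx) = H[i];
            P_rec(i, s.idx) = P[i];
          }
        } else {
          int i = iv_patch[s.idx];
          if (i < 0 || i >= N) stop("intervention patch out of range");
          int amt = iv_amount[s.idx];
          int* v = (iv_species[s.idx] == 0) ? &H[i] : &P[i];
          long before = *v;
          if (iv_action[s.idx] == 0) {            // set
            if (amt < 0) stop("cannot set abundance below zero");
            *v = amt;
          } else {                                 // add
            *v += amt;
            if (*v < 0) *v = 0;
          }
          total_pop += *v - before;
          double old = tot[i];
          tot[i] = patch_total(p, H[i], P[i]);
          S += tot[i] - old;
        }
        ++s_ptr;
      }
      if (s_ptr >= sched.size() && t >= t_end) break;
      continue;
    }
    t += dt;
    if (t >= t_end) break;

    // pick patch proportional to its total rate
    double u = unif_rand() * S;
    int i = 0;
    double acc = 0.0;
    for (; i < N - 1; ++i) {
      acc += tot[i];
      if (u < acc) break;
    }
    patch_rates(p, H[i], P[i], r8);
    double psum = r8[0] + r8[1] + r8[2] + r8[3] + r8[4] + r8[5] + r8[6] +
                  r8[7];
    if (psum <= 0.0) {  // stale floating-point total picked a dead patch
      S -= tot[i];
      tot[i] = 0.0;
      continue;
    }
    double pu = unif_rand() * psum;
    int ev = 0;
    double pacc = 0.0;
    for (; ev < 7; ++ev) {
      pacc += r8[ev];
      if (pu < pacc) break;
    }
    while (ev > 0 && r8[ev] <= 0.0) --ev;  // guard rounding fallthrough

    int j = -1;  // destination for emigration events
    switch (ev) {
      case 0: ++H[i]; ++total_pop; break;
      case 1: case 2: case 3: --H[i]; --total_pop; break;
      case 4: ++P[i]; ++total_pop; break;
      case 5: --P[i]; --total_pop; break;
      case 6: case 7: {
        double du = unif_rand();
        double dacc = 0.0;
        j = N;  // falls through to "outside" if rounding leaves a remainder
        for (int c = 0; c <= N; ++c) {
          dacc += settle(i, c);
          if (du < dacc) { j = c; break; }
        }
        if (ev == 6) {
          --H[i];
          if (j < N) ++H[j]; else { outside_H += 1.0; --total_pop; }
        } else {
          --P[i];
          if (j < N) ++P[j]; else { outside_P += 1.0; --total_pop; }
        }
        break;
      }
    }
    if (log_events) ev_counts[ev] += 1.0;
    if (total_pop > (long)p.pop_cap) {
      stop("total population exceeded pop_cap (%.0f): parameter pathology?",
           p.pop_cap);
    }

    double old_i = tot[i];
    tot[i] = patch_total(p, H[i], P[i]);
    S += tot[i] - old_i;
    if (j >= 0 && j < N && j != i) {
      double old_j = tot[j];
      tot[j] = patch_total(p, H[j], P[j]);
      S += tot[j] - old_j;
    }
    if (++steps_since_refresh >= 4096) {  // keep incremental S from drifting
      refresh_S();
      steps_since_refresh = 0;
    }
    if ((steps_since_refresh & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["H"] = H_rec, _["P"] = P_rec,
                      _["event_counts"] = ev_counts,
                      _["outside_H"] = outside_H,
                      _["outside_P"] = outside_P,
                      _["t_final"] = t_end);
}
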