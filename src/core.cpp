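#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Adjacency by source node: tgt[j] / w[j] list the targets and signed weights
// of node j's out-links. Built once per simulation call from the dense weight
// matrix W, where W(i, j) is the weight of the link j -> i.
struct Adjacency {
  int n;
  std::vector<std::vector<int> > tgt;
  std::vector<std::vector<int> > w;
  explicit Adjacency(const IntegerMatrix& W) {
    n = W.nrow();
    tgt.resize(n);
    w.resize(n);
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < n; ++i) {
        int wij = W(i, j);
        if (wij != 0) {
          tgt[j].push_back(i);
          w[j].push_back(wij);
        }
      }
    }
  }
};

// Synchronous stochastic (Glauber) updates over n_steps steps.
// Activation probability of node i is 1 / (1 + exp(-2 beta (f_i - theta_i - eps)))
// with integer input field f_i = sum_j w_ij n_j. Exactly N uniform draws are
// consumed per step, in node-index order. Returns the N x n_steps matrix of
// states after each step.
// [[Rcpp::export]]
IntegerMatrix cpp_run_window(const IntegerMatrix& W, const IntegerVector& theta,
                             double beta, double eps, const IntegerVector& s0,
                             int n_steps) {
  const int n = W.nrow();
  Adjacency adj(W);
  // input fields and thresholds are integers, so f - theta is in [-2n, 2n];
  // tabulating the logistic once removes exp() from the inner loop
  std::vector<double> plog(4 * n + 1);
  for (int m = -2 * n; m <= 2 * n; ++m)
    plog[m + 2 * n] = 1.0 / (1.0 + std::exp(-2.0 * beta * ((double)m - eps)));

  IntegerMatrix out(n, n_steps);
  std::vector<int> s(n), f(n, 0);
  for (int i = 0; i < n; ++i) s[i] = s0[i];

  for (int t = 0; t < n_steps; ++t) {
    std::fill(f.begin(), f.end(), 0);
    for (int j = 0; j < n; ++j) {
      if (s[j]) {
        const std::vector<int>& tg = adj.tgt[j];
        const std::vector<int>& wg = adj.w[j];
        for (size_t k = 0; k < tg.size(); ++k) f[tg[k]] += wg[k];
      }
    }
    for (int i = 0; i < n; ++i) {
      int m = f[i] - theta[i];
      double p = plog[m + 2 * n];
      s[i] = (unif_rand() < p) ? 1 : 0;
      out(i, t) = s[i];
    }
  }
  return out;
}

// One deterministic avalanche with the exhaust (threshold fatigue) mechanism.
// Contract: network starts all-off; the trigger node is set active at t = 1.
// Each step: (a) next state n_i = 1 iff f_i - theta_eff_i > 0, computed
// synchronously from the full current state; (b) every node still at its base
// threshold, with at least one active step within the last t_e steps, raises
// theta_eff by 1 with probability (active steps among last t_e) / t_e --
// one uniform per eligible node, drawn in node-index order; (c) advance.
// Terminates at the first all-off step; t_e <= 0 disables fatigue entirely.
static void one_avalanche(const Adjacency& adj, const IntegerVector& theta,
                          int trigger, int t_e, int max_steps, bool sticky,
                          bool record_events,
                          int& S, int& T, int& term, std::vector<int>& profile,
                          std::vector<int>& ev_t, std::vector<int>& ev_node) {
  const int n = adj.n;
  std::vector<int> theta_eff(n), f(n, 0);
  std::vector<char> elevated(n, 0), ever(n, 0), in_next(n, 0);
  std::vector<int> active, nxt, touched;
  std::vector<char> buf;
  std::vector<int> wincount;
  if (t_e > 0) {
    buf.assign((size_t)n * t_e, 0);
    wincount.assign(n, 0);
  }
  for (int i = 0; i < n; ++i) theta_eff[i] = theta[i];

  active.push_back(trigger);
  ever[trigger] = 1;
  profile.clear();
  profile.push_back(1);
  if (record_events) { ev_t.push_back(1); ev_node.push_back(trigger); }
  bool any_elev = false;
  int t = 1;
  term = 0;

  while (true) {
    // (a) synchronous next state from the current active set
    touched.clear();
    for (size_t a = 0; a < active.size(); ++a) {
      int j = active[a];
      const std::vector<int>& tg = adj.tgt[j];
      const std::vector<int>& wg = adj.w[j];
      for (size_t k = 0; k < tg.size(); ++k) {
        if (f[tg[k]] == 0) touched.push_back(tg[k]);
        f[tg[k]] += wg[k];
      }
    }
    nxt.clear();
    for (size_t k = 0; k < touched.size(); ++k) {
      int i = touched[k];
      // touched may hold duplicates (field returned to 0 and moved again) and
      // entries whose field cancelled back to zero; in_next dedupes
      if (f[i] != 0 && f[i] - theta_eff[i] > 0 && !in_next[i]) {
        in_next[i] = 1;
        nxt.push_back(i);
      }
      f[i] = 0;
    }
    std::sort(nxt.begin(), nxt.end());

    // (b) fatigue lottery on the state just left behind: evict the buffer slot
    // from step t - t_e, write the current active set, then every unelevated
    // recently-active node draws once
    if (t_e > 0) {
      int pos = (t - 1) % t_e;
      char* col = &buf[(size_t)pos * n];
      for (int i = 0; i < n; ++i) {
        if (col[i]) { wincount[i]--; col[i] = 0; }
      }
      for (size_t a = 0; a < active.size(); ++a) {
        int i = active[a];
        col[i] = 1;
        wincount[i]++;
      }
      if (sticky) {
        // once raised, a threshold stays raised until the avalanche ends
        for (int i = 0; i < n; ++i) {
          if (!elevated[i] && wincount[i] > 0) {
            if (unif_rand() * t_e < (double)wincount[i]) {
              theta_eff[i] += 1;
              elevated[i] = 1;
              any_elev = true;
            }
          }
        }
      } else {
        // transient fatigue: the elevation is redrawn every step, so a node
        // recovers as its recent activity leaves the exhaust window
        for (int i = 0; i < n; ++i) {
          int up = 0;
          if (wincount[i] > 0 && unif_rand() * t_e < (double)wincount[i]) {
            up = 1;
            any_elev = true;
          }
          theta_eff[i] = theta[i] + up;
        }
      }
    }

    // (c) advance
    for (size_t k = 0; k < nxt.size(); ++k) in_next[nxt[k]] = 0;
    t += 1;
    if (nxt.empty()) {
      T = t - 1;
      term = any_elev ? 1 : 0;
      break;
    }
    active.swap(nxt);
    profile.push_back((int)active.size());
    for (size_t k = 0; k < active.size(); ++k) {
      ever[active[k]] = 1;
      if (record_events) { ev_t.push_back(t); ev_node.push_back(active[k]); }
    }
    if (t >= max_steps) {
      T = t;
      term = 2;  // step cap hit; avalanche reported as truncated
      break;
    }
  }
  S = 0;
  for (int i = 0; i < n; ++i) S += ever[i];
}

// [[Rcpp::export]]
List cpp_run_avalanche(const IntegerMatrix& W, const IntegerVector& theta,
                       int trigger, int t_e, int max_steps, bool sticky,
                       bool record_events) {
  Adjacency adj(W);
  int S, T, term;
  std::vector<int> profile, ev_t, ev_node;
  one_avalanche(adj, theta, trigger, t_e, max_steps, sticky, record_events,
                S, T, term, profile, ev_t, ev_node);
  List out = List::create(_["S"] = S, _["T"] = T, _["term"] = term,
                          _["profile"] = wrap(profile));
  if (record_events) {
    out["event_t"] = wrap(ev_t);
    out["event_node"] = wrap(ev_node);
  }
  return out;
}

// Sequential ensemble: each avalanche starts from a fully quiescent network
// (exhaust state reset) at a uniformly drawn trigger node. One uniform draw
// selects each trigger ahead of the avalanche's own fatigue draws.
// [[Rcpp::export]]
List cpp_run_ensemble(const IntegerMatrix& W, const IntegerVector& theta,
                      int n_avalanches, int t_e, int max_steps, bool sticky,
                      bool keep_profiles) {
  Adjacency adj(W);
  const int n = adj.n;
  IntegerVector S(n_avalanches), T(n_avalanches), term(n_avalanches),
      trig(n_avalanches);
  List profiles = keep_profiles ? List(n_avalanches) : List(0);
  std::vector<int> profile, ev_t, ev_node;
  for (int a = 0; a < n_avalanches; ++a) {
    int trigger = (int)(unif_rand() * n);
    if (trigger >= n) trigger = n - 1;
    int s, tt, tm;
    one_avalanche(adj, theta, trigger, t_e, max_steps, sticky, false, s, tt, tm,
                  profile, ev_t, ev_node);
    S[a] = s;
    T[a] = tt;
    term[a] = tm;
    trig[a] = trigger + 1;  // 1-based for R
    if (keep_profiles) profiles[a] = wrap(profile);
    if ((a & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["S"] = S, _["T"] = T, _["term"] = term,
                          _["trigger"] = trig);
  if (keep_profiles) out["profiles"] = profiles;
  return out;
}
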