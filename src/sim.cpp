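#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Class coding used throughout: 0 = (S=+1, sigma=+1), 1 = (+1,-1),
// 2 = (-1,+1), 3 = (-1,-1).  First index public, second private.

static inline int cls_of(int S, int sg) {
  return (S > 0 ? 0 : 2) + (sg > 0 ? 0 : 1);
}

// number of +1 public opinions in a panel of q drawn without replacement
// from a pool with `plus` positives among `pool` agents
static inline int hyper_kplus(int plus, int pool, int q) {
  return (int) R::rhyper((double) plus, (double) (pool - plus), (double) q);
}

// public-level update given panel composition k (+1 count among q).
// Conflict rule: switch to sigma if >= 1 panel member shares it; harmony
// rule: adopt the panel's opinion only under unanimity.
static inline int public_conformity(int S, int sg, int k, int q) {
  if (S != sg) {
    bool any_match = (sg > 0) ? (k >= 1) : (k <= q - 1);
    return any_match ? sg : S;
  }
  if (k == q) return 1;
  if (k == 0) return -1;
  return S;
}

static inline int private_conformity(int sg, int k, int q) {
  if (k == q) return 1;
  if (k == 0) return -1;
  return sg;
}

// Random sequential dynamics on the complete graph in the compressed
// four-class representation: only the counts (n_pp, n_pm, n_mp, n_mm) are
// tracked and the focal agent's panels are drawn hypergeometrically from
// the N-1 non-focal agents.  Statistically equivalent to the per-agent
// engine on the complete graph, but O(1) memory in N.
// Returns an integer matrix: t (MCS), n_pp, n_pm, n_mp, n_mm.
// [[Rcpp::export]]
IntegerMatrix sim_counts_cpp(IntegerVector counts0, int q, double p,
                             bool at_order, int horizon, int record_every) {
  long long n[4];
  long long N = 0;
  for (int j = 0; j < 4; ++j) { n[j] = counts0[j]; N += n[j]; }
  if (q >= N) stop("q must be smaller than N on the complete graph");

  int n_rec = horizon / record_every + 1;
  IntegerMatrix out(n_rec, 5);
  int rec = 0;
  out(rec, 0) = 0;
  for (int j = 0; j < 4; ++j) out(rec, j + 1) = (int) n[j];
  ++rec;

  RNGScope scope;
  for (int t = 1; t <= horizon; ++t) {
    for (long long step = 0; step < N; ++step) {
      // focal class ~ current counts
      double u = unif_rand() * N;
      int cls = 0;
      double acc = (double) n[0];
      while (cls < 3 && u >= acc) { acc += (double) n[++cls]; }
      int S  = (cls < 2) ? 1 : -1;
      int sg = (cls % 2 == 0) ? 1 : -1;

      long long NS = n[0] + n[1];              // public +1 count
      int pool = (int) (N - 1);
      int plus = (int) (NS - (S > 0 ? 1 : 0)); // exclude the focal agent

      int S1 = S, sg1 = sg;
      if (at_order) {
        if (unif_rand() < p) {
          S1 = sg;
        } else {
          S1 = public_conformity(S, sg, hyper_kplus(plus, pool, q), q);
        }
        if (unif_rand() < p) {
          sg1 = (unif_rand() < 0.5) ? -sg : sg;
        } else {
          sg1 = private_conformity(sg, hyper_kplus(plus, pool, q), q);
        }
      } else {
        if (unif_rand() < p) {
          sg1 = (unif_rand() < 0.5) ? -sg : sg;
        } else {
          sg1 = private_conformity(sg, hyper_kplus(plus, pool, q), q);
        }
        if (unif_rand() < p) {
          S1 = sg1;
        } else {
          S1 = public_conformity(S, sg1, hyper_kplus(plus, pool, q), q);
        }
      }
      int cls1 = cls_of(S1, sg1);
      if (cls1 != cls) { --n[cls]; ++n[cls1]; }
    }
    if (t % record_every == 0) {
      out(rec, 0) = t;
      for (int j = 0; j < 4; ++j) out(rec, j + 1) = (int) n[j];
      ++rec;
    }
  }
  return out;
}

// Per-agent engine on an arbitrary network (adj empty => complete graph).
// Optionally records the first max_events influence events with the
// exerted source position resolved by the package's instrumentation
// convention (see tally_events()).
// [[Rcpp::export]]
List sim_agents_cpp(IntegerVector S0, IntegerVector sigma0, List adj,
                    int q, double p, bool at_order,
                    int horizon, int record_every, int max_events) {
  int N = S0.size();
  bool complete = (adj.size() == 0);
  std::vector<int> S(S0.begin(), S0.end());
  std::vector<int> sg(sigma0.begin(), sigma0.end());
  std::vector< std::vector<int> > nb;
  if (!complete) {
    nb.resize(N);
    for (int i = 0; i < N; ++i) {
      IntegerVector v = adj[i];
      if ((int) v.size() < q)
        stop("vertex %d has degree %d < q = %d", i + 1, (int) v.size(), q);
      nb[i].assign(v.begin(), v.end());
      for (size_t j = 0; j < nb[i].size(); ++j) nb[i][j] -= 1; // 1- to 0-based
    }
  } else if (q >= N) {
    stop("q must be smaller than N on the complete graph");
  }

  long long n[4] = {0, 0, 0, 0};
  for (int i = 0; i < N; ++i) ++n[cls_of(S[i], sg[i])];

  int n_rec = horizon / record_every + 1;
  IntegerMatrix out(n_rec, 5);
  int rec = 0;
  out(rec, 0) = 0;
  for (int j = 0; j < 4; ++j) out(rec, j + 1) = (int) n[j];
  ++rec;

  IntegerMatrix ev(max_events, 7);  // pre_pub pre_priv post_pub post_priv src chan_pub chan_priv
  int n_ev = 0;

  RNGScope scope;
  std::vector<int> panel(q);

  // draws a panel of q distinct neighbours of i; fills `panel` with their
  // public opinions; returns the +1 count
  auto draw_panel = [&](int i) {
    if (complete) {
      long long NS = n[0] + n[1];
      int plus = (int) (NS - (S[i] > 0 ? 1 : 0));
      int k = hyper_kplus(plus, N - 1, q);
      for (int j = 0; j < q; ++j) panel[j] = (j < k) ? 1 : -1;
      return k;
    }
    std::vector<int> &v = nb[i];
    int d = (int) v.size();
    int k = 0;
    for (int j = 0; j < q; ++j) {
      int r = j + (int) (unif_rand() * (d - j));
      if (r >= d) r = d - 1;
      std::swap(v[j], v[r]);
      panel[j] = S[v[j]];
      if (panel[j] > 0) ++k;
    }
    return k;
  };

  for (int t = 1; t <= horizon; ++t) {
    for (int step = 0; step < N; ++step) {
      int i = (int) (unif_rand() * N);
      if (i >= N) i = N - 1;
      int s_pre = S[i], sg_pre = sg[i];
      int S1 = s_pre, sg1 = sg_pre;
      // per-level channel (1 = conformity) and exerted source position
      int chan_pub = 0, chan_priv = 0, src_pub = 0, src_priv = 0;

      auto public_step = [&](int s_cur, int sg_cur) {
        if (unif_rand() < p) { chan_pub = 0; return sg_cur; }
        chan_pub = 1;
        int k = draw_panel(i);
        if (s_cur != sg_cur) {
          bool any_match = (sg_cur > 0) ? (k >= 1) : (k <= q - 1);
          // a mixed panel always contains sigma; a panel with no member
          // matching sigma is unanimous against it
          src_pub = any_match ? sg_cur : -sg_cur;
          return any_match ? sg_cur : s_cur;
        }
        if (k == q) { src_pub = 1;  return 1; }
        if (k == 0) { src_pub = -1; return -1; }
        src_pub = panel[(int) (unif_rand() * q)];  // mixed panel spokesperson
        return s_cur;
      };
      auto private_step = [&](int sg_cur) {
        if (unif_rand() < p) {
          chan_priv = 0;
          return (unif_rand() < 0.5) ? -sg_cur : sg_cur;
        }
        chan_priv = 1;
        int k = draw_panel(i);
        if (k == q) { src_priv = 1;  return 1; }
        if (k == 0) { src_priv = -1; return -1; }
        src_priv = panel[(int) (unif_rand() * q)];
        return sg_cur;
      };

      if (at_order) {
        S1 = public_step(s_pre, sg_pre);
        sg1 = private_step(sg_pre);
      } else {
        sg1 = private_step(sg_pre);
        S1 = public_step(s_pre, sg1);
      }

      if (n_ev < max_events) {
        int src = chan_pub ? src_pub : (chan_priv ? src_priv : 0);
        ev(n_ev, 0) = s_pre;  ev(n_ev, 1) = sg_pre;
        ev(n_ev, 2) = S1;     ev(n_ev, 3) = sg1;
        ev(n_ev, 4) = src;    ev(n_ev, 5) = chan_pub; ev(n_ev, 6) = chan_priv;
        ++n_ev;
      }

      int c0 = cls_of(s_pre, sg_pre), c1 = cls_of(S1, sg1);
      if (c0 != c1) { --n[c0]; ++n[c1]; }
      S[i] = S1; sg[i] = sg1;
    }
    if (t % record_every == 0) {
      out(rec, 0) = t;
      for (int j = 0; j < 4; ++j) out(rec, j + 1) = (int) n[j];
      ++rec;
    }
  }

  return List::create(_["counts"] = out,
                      _["events"] = ev,
                      _["n_events"] = n_ev,
                      _["S"] = IntegerVector(S.begin(), S.end()),
                      _["sigma"] = IntegerVector(sg.begin(), sg.end()));
}
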