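// Built-in nearest-neighbor MFE folding engine.
//
// Zuker-style dynamic program over nested structures with canonical pairs
// (AU, UA, CG, GC, GU, UG), minimum hairpin loop of 3 unpaired nt, stacking
// energies from a small embedded parameter table passed in from R,
// logarithmic hairpin/bulge/internal-loop penalties and a linear multiloop
// model. No dangling ends, no coaxial stacking. Interior/bulge loops are
// capped at `max_loop` unpaired nt in the DP (standard practice).
//
// Chemical-modification constraints: a flagged position may not sit in a
// pair that is flanked on BOTH sides by pairs (helix-internal position).
// Handled by splitting the paired array V into two variants:
//   V0(i,j): (i,j) paired, the enclosing positions (i-1,j+1) do NOT pair
//   V1(i,j): (i,j) paired, (i-1,j+1) DO pair with each other (helix outside)
// In V1, when i or j is flagged, the immediate-stack transition (which is
// the only way (i+1,j-1) can pair with each other) is forbidden.
//
// Energies are integer decacal (kcal/mol * 100) internally.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int INF = std::numeric_limits<int>::max() / 4;

struct Params {
  int stack[6][6];           // [outer pair type][inner pair type]
  std::vector<int> hairpin;  // by loop length
  std::vector<int> bulge;
  std::vector<int> intl;     // by total unpaired (n1 + n2)
  int ml_close, ml_branch, ml_unpaired;
  int max_loop;
  int min_hairpin;
};

// base codes: A=0, C=1, G=2, U=3
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static Params make_params(const List& par, int n) {
  Params p;
  NumericMatrix st = par["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j)
      p.stack[i][j] = (int)std::lround(100.0 * st(i, j));
  double ha = par["hairpin_a"], hb = par["hairpin_b"];
  double ba = par["bulge_a"],  bb = par["bulge_b"];
  double ia = par["intl_a"],   ib = par["intl_b"];
  p.ml_close    = (int)std::lround(100.0 * as<double>(par["ml_close"]));
  p.ml_branch   = (int)std::lround(100.0 * as<double>(par["ml_branch"]));
  p.ml_unpaired = (int)std::lround(100.0 * as<double>(par["ml_unpaired"]));
  p.max_loop    = as<int>(par["max_loop"]);
  p.min_hairpin = as<int>(par["min_hairpin"]);
  int m = n + 2;
  p.hairpin.assign(m, INF);
  p.bulge.assign(m, INF);
  p.intl.assign(m, INF);
  for (int L = p.min_hairpin; L < m; ++L)
    p.hairpin[L] = (int)std::lround(100.0 * (ha + hb * std::log((double)L / p.min_hairpin)));
  for (int L = 1; L < m; ++L)
    p.bulge[L] = (int)std::lround(100.0 * (ba + bb * std::log((double)L)));
  for (int L = 2; L < m; ++L)
    p.intl[L] = (int)std::lround(100.0 * (ia + ib * std::log((double)L / 2.0)));
  return p;
}

struct FoldDP {
  int n;
  const std::vector<int>& s;
  const std::vector<bool>& mod;
  const Params& P;
  std::vector<int> V0, V1, ML, M1, W;
  FoldDP(const std::vector<int>& seq, const std::vector<bool>& m, const Params& par)
    : n((int)seq.size()), s(seq), mod(m), P(par),
      V0((size_t)n * n, INF), V1((size_t)n * n, INF),
      ML((size_t)n * n, INF), M1((size_t)n * n, INF), W(n + 1, 0) {}

  inline size_t ix(int i, int j) const { return (size_t)i * n + j; }
  inline bool can_pair(int i, int j) const {
    return j - i > P.min_hairpin && pair_type(s[i], s[j]) >= 0;
  }

  // energy of pair (i,j) given outer-stacked status o, with all inner
  // tables already filled
  int pair_energy(int i, int j, int o) const {
    if (!can_pair(i, j)) return INF;
    int best = P.hairpin[j - i - 1];
    // immediate stack
    if (can_pair(i + 1, j - 1)) {
      bool forbidden = (o == 1) && (mod[i] || mod[j]);
      if (!forbidden && V1[ix(i + 1, j - 1)] < INF) {
        int e = P.stack[pair_type(s[i], s[j])][pair_type(s[i + 1], s[j - 1])]
                + V1[ix(i + 1, j - 1)];
        if (e < best) best = e;
      }
    }
    // bulge / interior loops (n1 + n2 >= 1)
    for (int n1 = 0; n1 <= P.max_loop; ++n1) {
      int k = i + 1 + n1;
      if (k >= j - 1) break;
      for (int n2 = (n1 == 0 ? 1 : 0); n1 + n2 <= P.max_loop; ++n2) {
        int l = j - 1 - n2;
        if (l <= k) break;
        if (V0[ix(k, l)] >= INF) continue;
        int pen = (n1 == 0 || n2 == 0) ? P.bulge[n1 + n2] : P.intl[n1 + n2];
        int e = pen + V0[ix(k, l)];
        if (e < best) best = e;
      }
    }
    // multiloop: >= 2 branches inside
    for (int k = i + 2; k <= j - 2; ++k) {
      if (ML[ix(i + 1, k - 1)] >= INF || M1[ix(k, j - 1)] >= INF) continue;
      int e = P.ml_close + P.ml_branch + ML[ix(i + 1, k - 1)] + M1[ix(k, j - 1)];
      if (e < best) best = e;
    }
    return best;
  }

  void fill() {
    for (int d = P.min_hairpin + 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        V0[ix(i, j)] = pair_energy(i, j, 0);
        V1[ix(i, j)] = pair_energy(i, j, 1);
        // M1: exactly one branch whose 5' end is i; trailing unpaired to j
        int m1 = INF;
        if (j - 1 >= i && M1[ix(i, j - 1)] < INF)
          m1 = M1[ix(i, j - 1)] + P.ml_unpaired;
        if (V0[ix(i, j)] < INF)
          m1 = std::min(m1, V0[ix(i, j)] + P.ml_branch);
        M1[ix(i, j)] = m1;
        // ML: >= 1 branch anywhere in [i, j]
        int ml = INF;
        if (i + 1 <= j && ML[ix(i + 1, j)] < INF) ml = ML[ix(i + 1, j)] + P.ml_unpaired;
        if (j - 1 >= i && ML[ix(i, j - 1)] < INF)
          ml = std::min(ml, ML[ix(i, j - 1)] + P.ml_unpaired);
        if (V0[ix(i, j)] < INF) ml = std::min(ml, V0[ix(i, j)] + P.ml_branch);
        for (int k = i + 1; k <= j; ++k) {
          if (ML[ix(i, k - 1)] >= INF || M1[ix(k, j)] >= INF) continue;
          ml = std::min(ml, ML[ix(i, k - 1)] + M1[ix(k, j)]);
        }
        ML[ix(i, j)] = ml;
      }
    }
    // exterior
    W[0] = 0;  // W[j+1] = best over prefix [0, j]
    for (int j = 0; j < n; ++j) {
      int w = W[j];
      for (int k = 0; k <= j; ++k) {
        if (V0[ix(k, j)] >= INF) continue;
        int e = (k > 0 ? W[k] : 0) + V0[ix(k, j)];
        if (e < w) w = e;
      }
      W[j + 1] = w;
    }
  }

  // ---- traceback --------------------------------------------------------
  void trace_V(int i, int j, int o, std::vector<int>& partner) const {
    partner[i] = j; partner[j] = i;
    int target = (o == 0) ? V0[ix(i, j)] : V1[ix(i, j)];
    if (target == P.hairpin[j - i - 1]) return;
    if (can_pair(i + 1, j - 1)) {
      bool forbidden = (o == 1) && (mod[i] || mod[j]);
      if (!forbidden && V1[ix(i + 1, j - 1)] < INF) {
        int e = P.stack[pair_type(s[i], s[j])][pair_type(s[i + 1], s[j - 1])]
                + V1[ix(i + 1, j - 1)];
        if (e == target) { trace_V(i + 1, j - 1, 1, partner); return; }
      }
    }
    for (int n1 = 0; n1 <= P.max_loop; ++n1) {
      int k = i + 1 + n1;
      if (k >= j - 1) break;
      for (int n2 = (n1 == 0 ? 1 : 0); n1 + n2 <= P.max_loop; ++n2) {
        int l = j - 1 - n2;
        if (l <= k) break;
        if (V0[ix(k, l)] >= INF) continue;
        int pen = (n1 == 0 || n2 == 0) ? P.bulge[n1 + n2] : P.intl[n1 + n2];
        if (pen + V0[ix(k, l)] == target) { trace_V(k, l, 0, partner); return; }
      }
    }
    for (int k = i + 2; k <= j - 2; ++k) {
      if (ML[ix(i + 1, k - 1)] >= INF || M1[ix(k, j - 1)] >= INF) continue;
      if (P.ml_close + P.ml_branch + ML[ix(i + 1, k - 1)] + M1[ix(k, j - 1)] == target) {
        trace_ML(i + 1, k - 1, partner);
        trace_M1(k, j - 1, partner);
        return;
      }
    }
    stop("internal error: traceback failed in V");
  }

  void trace_M1(int i, int j, std::vector<int>& partner) const {
    int target = M1[ix(i, j)];
    if (V0[ix(i, j)] < INF && V0[ix(i, j)] + P.ml_branch == target) {
      trace_V(i, j, 0, partner); return;
    }
    if (j - 1 >= i && M1[ix(i, j - 1)] < INF &&
        M1[ix(i, j - 1)] + P.ml_unpaired == target) {
      trace_M1(i, j - 1, partner); return;
    }
    stop("internal error: traceback failed in M1");
  }

  void trace_ML(int i, int j, std::vector<int>& partner) const {
    int target = ML[ix(i, j)];
    if (V0[ix(i, j)] < INF && V0[ix(i, j)] + P.ml_branch == target) {
      trace_V(i, j, 0, partner); return;
    }
    if (i + 1 <= j && ML[ix(i + 1, j)] < INF &&
        ML[ix(i + 1, j)] + P.ml_unpaired == target) {
      trace_ML(i + 1, j, partner); return;
    }
    if (j - 1 >= i && ML[ix(i, j - 1)] < INF &&
        ML[ix(i, j - 1)] + P.ml_unpaired == target) {
      trace_ML(i, j - 1, partner); return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (ML[ix(i, k - 1)] >= INF || M1[ix(k, j)] >= INF) continue;
      if (ML[ix(i, k - 1)] + M1[ix(k, j)] == target) {
        trace_ML(i, k - 1, partner);
        trace_M1(k, j, partner);
        return;
      }
    }
    stop("internal error: traceback failed in ML");
  }

  void trace_W(std::vector<int>& partner) const {
    int j = n - 1;
    while (j >= 0) {
      if (W[j + 1] == W[j]) { --j; continue; }
      bool found = false;
      for (int k = 0; k <= j; ++k) {
        if (V0[ix(k, j)] >= INF) continue;
        if ((k > 0 ? W[k] : 0) + V0[ix(k, j)] == W[j + 1]) {
          trace_V(k, j, 0, partner);
          j = k - 1;
          found = true;
          break;
        }
      }
      if (!found) stop("internal error: traceback failed in W");
    }
  }
};

static std::vector<int> as_seq(const IntegerVector& seq) {
  std::vector<int> s(seq.size());
  for (int i = 0; i < (int)seq.size(); ++i) {
    if (seq[i] < 0 || seq[i] > 3) stop("sequence codes must be in 0..3");
    s[i] = seq[i];
  }
  return s;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq, LogicalVector modified, List params) {
  int n = seq.size();
  if (n == 0) return List::create(_["i"] = IntegerVector(0),
                                  _["j"] = IntegerVector(0),
                                  _["energy"] = 0.0);
  if (modified.size() != n) stop("modified mask length mismatch");
  std::vector<int> s = as_seq(seq);
  std::vector<bool> mod(n);
  for (int i = 0; i < n; ++i) mod[i] = modified[i];
  Params P = make_params(params, n);
  FoldDP dp(s, mod, P);
  dp.fill();
  std::vector<int> partner(n, -1);
  dp.trace_W(partner);
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i)
    if (partner[i] > i) { pi.push_back(i + 1); pj.push_back(partner[i] + 1); }
  return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                      _["energy"] = dp.W[n] / 100.0);
}

// [[Rcpp::export(name = ".eval_energy_cpp")]]
double eval_energy_cpp(IntegerVector seq, IntegerVector pair_i,
                       IntegerVector pair_j, List params) {
  int n = seq.size();
  std::vector<int> s = as_seq(seq);
  Params P = make_params(params, n);
  std::vector<int> partner(n, -1);
  for (int k = 0; k < pair_i.size(); ++k) {
    int i = pair_i[k] - 1, j = pair_j[k] - 1;
    if (i < 0 || j >= n || i >= j) stop("invalid pair");
    if (partner[i] != -1 || partner[j] != -1) stop("position in more than one pair");
    if (pair_type(s[i], s[j]) < 0) stop("non-canonical pair in structure");
    if (j - i <= P.min_hairpin) stop("hairpin loop shorter than minimum");
    partner[i] = j; partner[j] = i;
  }
  // loop decomposition; process exterior plus every closing pair
  long total = 0;
  std::vector<std::pair<int,int>> stack_iv;
  stack_iv.push_back(std::make_pair(-1, n));  // virtual exterior pair
  while (!stack_iv.empty()) {
    int i = stack_iv.back().first, j = stack_iv.back().second;
    stack_iv.pop_back();
    std::vector<std::pair<int,int>> children;
    int k = i + 1;
    while (k < j) {
      if (partner[k] > k) {
        if (partner[k] >= j) stop("crossing (pseudoknotted) pairs");
        children.push_back(std::make_pair(k, partner[k]));
        k = partner[k] + 1;
      } else if (partner[k] != -1 && partner[k] < i) {
        stop("crossing (pseudoknotted) pairs");
      } else {
        ++k;
      }
    }
    if (i >= 0) {
      int nc = (int)children.size();
      if (nc == 0) {
        total += P.hairpin[j - i - 1];
      } else if (nc == 1) {
        int ci = children[0].first, cj = children[0].second;
        int n1 = ci - i - 1, n2 = j - cj - 1;
        if (n1 == 0 && n2 == 0)
          total += P.stack[pair_type(s[i], s[j])][pair_type(s[ci], s[cj])];
        else if (n1 == 0 || n2 == 0)
          total += P.bulge[n1 + n2];
        else
          total += P.intl[n1 + n2];
      } else {
        int unpaired = j - i - 1;
        for (int c = 0; c < nc; ++c)
          unpaired -= children[c].second - children[c].first + 1;
        total += P.ml_close + P.ml_branch * (nc + 1) + P.ml_unpaired * unpaired;
      }
    }
    for (size_t c = 0; c < children.size(); ++c) stack_iv.push_back(children[c]);
  }
  return total / 100.0;
}
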