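// Tree kernels for the taxon influence index.
//
// Trees arrive as ape-style integer edge matrices (1-based node ids, tips
// 1..ntips, internal nodes ntips+1..) whose tip ids have already been
// aligned to a shared label ordering on the R side.  All kernels work on a
// plain adjacency-list view of the unrooted tree.  Bipartitions are encoded
// as 64-bit masks over tip ids (hence the ntips <= 64 limit enforced in R),
// normalised to the side not containing tip 1 so each split has one code.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <climits>
#include <unordered_map>
#include <string>
#include <vector>
#include <array>
#include <algorithm>
#include <functional>

using namespace Rcpp;

typedef std::vector<std::vector<int>> Adj;

static Adj build_adj(const IntegerMatrix& edge, int* nnodes_out) {
  int nnodes = 0;
  for (int i = 0; i < edge.nrow(); ++i) {
    nnodes = std::max(nnodes, std::max(edge(i, 0), edge(i, 1)));
  }
  Adj adj(nnodes);
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  if (nnodes_out) *nnodes_out = nnodes;
  return adj;
}

// Nontrivial splits of an unrooted tree, as sorted normalised tip masks.
static void tree_splits(const Adj& adj, int ntips, std::vector<uint64_t>& out) {
  const int nn = (int)adj.size();
  std::vector<int> parent(nn, -2), order;
  order.reserve(nn);
  std::vector<int> st;
  st.push_back(0);
  parent[0] = -1;
  while (!st.empty()) {
    int u = st.back();
    st.pop_back();
    order.push_back(u);
    for (int w : adj[u])
      if (parent[w] == -2) {
        parent[w] = u;
        st.push_back(w);
      }
  }
  std::vector<uint64_t> mask(nn, 0);
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    if (u < ntips) mask[u] |= (1ULL << u);
    if (parent[u] >= 0) mask[parent[u]] |= mask[u];
  }
  const uint64_t full = (ntips == 64) ? ~0ULL : ((1ULL << ntips) - 1);
  out.clear();
  for (int u = 0; u < nn; ++u) {
    if (parent[u] < 0) continue;
    uint64_t m = mask[u];
    if (m & 1ULL) m ^= full;
    int pc = __builtin_popcountll(m);
    if (pc >= 2 && pc <= ntips - 2) out.push_back(m);
  }
  std::sort(out.begin(), out.end());
}

static std::string splits_raw_key(const std::vector<uint64_t>& s) {
  std::string k;
  k.resize(s.size() * sizeof(uint64_t));
  if (!s.empty()) std::memcpy(&k[0], s.data(), k.size());
  return k;
}

// Symmetric-difference count of two sorted split lists.
static int rf_from_splits(const std::vector<uint64_t>& a,
                          const std::vector<uint64_t>& b) {
  size_t i = 0, j = 0;
  int d = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++i; ++j; }
    else if (a[i] < b[j]) { ++d; ++i; }
    else { ++d; ++j; }
  }
  d += (int)(a.size() - i) + (int)(b.size() - j);
  return d;
}

static inline void rm_nb(Adj& a, int u, int v) {
  auto& x = a[u];
  x.erase(std::find(x.begin(), x.end(), v));
  auto& y = a[v];
  y.erase(std::find(y.begin(), y.end(), u));
}
static inline void add_nb(Adj& a, int u, int v) {
  a[u].push_back(v);
  a[v].push_back(u);
}

// Enumerate all unrooted SPR neighbours of a binary tree, in a fixed
// canonical order (prune edges by node id, regraft edges by node id).
// Regrafting onto the edge created by suppressing the prune point is a
// no-op and never generated.
template <typename F>
static void for_each_spr_neighbor(const Adj& adj, F f) {
  const int nn = (int)adj.size();
  std::vector<char> pruned(nn);
  std::vector<int> st;
  for (int u = 0; u < nn; ++u) {
    if (adj[u].size() != 3) continue;  // prune point must be internal
    for (int v : adj[u]) {
      // component of v once edge (u, v) is cut; u blocks the only path back
      std::fill(pruned.begin(), pruned.end(), 0);
      st.clear();
      st.push_back(v);
      pruned[v] = 1;
      while (!st.empty()) {
        int w = st.back();
        st.pop_back();
        for (int z : adj[w]) {
          if (z == u || pruned[z]) continue;
          pruned[z] = 1;
          st.push_back(z);
        }
      }
      int a = -1, b = -1;
      for (int z : adj[u])
        if (z != v) {
          if (a < 0) a = z; else b = z;
        }
      for (int x = 0; x < nn; ++x) {
        if (pruned[x] || x == u) continue;
        for (int y : adj[x]) {
          if (y <= x || pruned[y] || y == u) continue;
          Adj c(adj);
          rm_nb(c, u, a);
          rm_nb(c, u, b);
          add_nb(c, a, b);
          rm_nb(c, x, y);
          add_nb(c, x, u);
          add_nb(c, u, y);
          f(c);
        }
      }
    }
  }
}

// ---------------------------------------------------------------- rooted MAST

struct Rooted {
  int root;
  std::vector<std::array<int, 2>> ch;
  std::vector<uint64_t> mask;
  std::vector<int> post;
};

static Rooted root_at_leaf(const Adj& adj, int ntips, int r) {
  const int nn = (int)adj.size();
  Rooted R;
  R.ch.assign(nn, {-1, -1});
  R.mask.assign(nn, 0);
  R.root = adj[r][0];
  std::vector<std::pair<int, int>> st;
  std::vector<int> pre;
  st.push_back({R.root, r});
  while (!st.empty()) {
    int u = st.back().first, p = st.back().second;
    st.pop_back();
    pre.push_back(u);
    int c = 0;
    for (int w : adj[u])
      if (w != p) {
        R.ch[u][c++] = w;
        st.push_back({w, u});
      }
  }
  R.post.assign(pre.rbegin(), pre.rend());
  for (int u : R.post) {
    if (u < ntips) R.mask[u] = (1ULL << u);
    else R.mask[u] = R.mask[R.ch[u][0]] | R.mask[R.ch[u][1]];
  }
  return R;
}

// Size of the maximum agreement subtree between two rooted binary trees
// sharing tip ids; fills M (nn1*nn2, row-major by node id).
static int rmast_dp(const Rooted& A, const Rooted& B, int ntips,
                    std::vector<int>& M, int nn) {
  for (int u : A.post) {
    for (int v : B.post) {
      int val;
      if (u < ntips && v < ntips) val = (u == v) ? 1 : 0;
      else if (u < ntips) val = (int)((B.mask[v] >> u) & 1ULL);
      else if (v < ntips) val = (int)((A.mask[u] >> v) & 1ULL);
      else {
        int u1 = A.ch[u][0], u2 = A.ch[u][1];
        int v1 = B.ch[v][0], v2 = B.ch[v][1];
        val = std::max(M[u1 * nn + v1] + M[u2 * nn + v2],
                       M[u1 * nn + v2] + M[u2 * nn + v1]);
        val = std::max(val, std::max(M[u1 * nn + v], M[u2 * nn + v]));
        val = std::max(val, std::max(M[u * nn + v1], M[u * nn + v2]));
      }
      M[u * nn + v] = val;
    }
  }
  return M[A.root * nn + B.root];
}

static uint64_t rmast_trace(const Rooted& A, const Rooted& B, int ntips,
                            const std::vector<int>& M, int nn, int u, int v) {
  if (u < ntips && v < ntips) return (u == v) ? (1ULL << u) : 0ULL;
  if (u < ntips) return ((B.mask[v] >> u) & 1ULL) ? (1ULL << u) : 0ULL;
  if (v < ntips) return ((A.mask[u] >> v) & 1ULL) ? (1ULL << v) : 0ULL;
  int u1 = A.ch[u][0], u2 = A.ch[u][1];
  int v1 = B.ch[v][0], v2 = B.ch[v][1];
  int target = M[u * nn + v];
  if (M[u1 * nn + v1] + M[u2 * nn + v2] == target)
    return rmast_trace(A, B, ntips, M, nn, u1, v1) |
           rmast_trace(A, B, ntips, M, nn, u2, v2);
  if (M[u1 * nn + v2] + M[u2 * nn + v1] == target)
    return rmast_trace(A, B, ntips, M, nn, u1, v2) |
           rmast_trace(A, B, ntips, M, nn, u2, v1);
  if (M[u1 * nn + v] == target) return rmast_trace(A, B, ntips, M, nn, u1, v);
  if (M[u2 * nn + v] == target) return rmast_trace(A, B, ntips, M, nn, u2, v);
  if (M[u * nn + v1] == target) return rmast_trace(A, B, ntips, M, nn, u, v1);
  return rmast_trace(A, B, ntips, M, nn, u, v2);
}

// Unrooted MAST = max over shared root leaves r of rooted MAST of the two
// trees re-rooted at r, plus the leaf r itself (any agreement subtree of
// size >= 1 contains some leaf).
static int mast_core(const Adj& A, const Adj& B, int ntips, uint64_t* witness) {
  const int nn = std::max(A.size(), B.size());
  std::vector<int> M(nn * nn);
  int best = -1, best_r = 0;
  for (int r = 0; r < ntips; ++r) {
    Rooted RA = root_at_leaf(A, ntips, r);
    Rooted RB = root_at_leaf(B, ntips, r);
    int val = rmast_dp(RA, RB, ntips, M, nn) + 1;
    if (val > best) {
      best = val;
      best_r = r;
    }
  }
  if (witness) {
    Rooted RA = root_at_leaf(A, ntips, best_r);
    Rooted RB = root_at_leaf(B, ntips, best_r);
    rmast_dp(RA, RB, ntips, M, nn);
    *witness = rmast_trace(RA, RB, ntips, M, nn, RA.root, RB.root) |
               (1ULL << best_r);
  }
  return best;
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export(name = ".tree_key_cpp")]]
std::string tree_key_cpp(IntegerMatrix edge, int ntips) {
  Adj adj = build_adj(edge, nullptr);
  std::vector<uint64_t> s;
  tree_splits(adj, ntips, s);
  std::string out;
  char buf[20];
  for (size_t i = 0; i < s.size(); ++i) {
    std::snprintf(buf, sizeof(buf), "%llx", (unsigned long long)s[i]);
    if (i) out += ",";
    out += buf;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_cpp")]]
int rf_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntips) {
  Adj a1 = build_adj(e1, nullptr), a2 = build_adj(e2, nullptr);
  std::vector<uint64_t> s1, s2;
  tree_splits(a1, ntips, s1);
  tree_splits(a2, ntips, s2);
  return rf_from_splits(s1, s2);
}

// [[Rcpp::export(name = ".mast_cpp")]]
List mast_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntips) {
  Adj a1 = build_adj(e1, nullptr), a2 = build_adj(e2, nullptr);
  uint64_t w = 0;
  int size = mast_core(a1, a2, ntips, &w);
  IntegerVector tips;
  for (int i = 0; i < ntips; ++i)
    if ((w >> i) & 1ULL) tips.push_back(i + 1);
  return List::create(_["size"] = size, _["tips"] = tips);
}

// [[Rcpp::export(name = ".spr_neighbors_cpp")]]
List spr_neighbors_cpp(IntegerMatrix edge, int ntips) {
  Adj adj = build_adj(edge, nullptr);
  std::vector<Adj> nbrs;   // collected in plain C++; R objects built after
  for_each_spr_neighbor(adj, [&](const Adj& c) { nbrs.push_back(c); });
  List out((int)nbrs.size());
  for (size_t t = 0; t < nbrs.size(); ++t) {
    const Adj& c = nbrs[t];
    int ne = 0;
    for (size_t u = 0; u < c.size(); ++u) ne += (int)c[u].size();
    ne /= 2;
    IntegerMatrix m(ne, 2);
    int k = 0;
    for (int u = 0; u < (int)c.size(); ++u)
      for (int v : c[u])
        if (v > u) {
          m(k, 0) = u + 1;
          m(k, 1) = v + 1;
          ++k;
        }
    out[t] = m;
  }
  return out;
}

// Bidirectional breadth-first search over the SPR graph with canonical-form
// deduplication.  status: 0 = exact distance found, 1 = depth cap hit,
// 2 = state cap hit (distance then -1).
// [[Rcpp::export(name = ".spr_exact_cpp")]]
List spr_exact_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntips,
                   int max_depth, int max_states) {
  Adj a1 = build_adj(e1, nullptr), a2 = build_adj(e2, nullptr);
  std::vector<uint64_t> s1, s2;
  tree_splits(a1, ntips, s1);
  tree_splits(a2, ntips, s2);
  std::string k1 = splits_raw_key(s1), k2 = splits_raw_key(s2);
  if (k1 == k2) return List::create(_["distance"] = 0, _["status"] = 0);

  std::unordered_map<std::string, int> visA, visB;
  visA[k1] = 0;
  visB[k2] = 0;
  std::vector<Adj> frontA{a1}, frontB{a2};
  int dA = 0, dB = 0;
  std::vector<uint64_t> s;

  // After complete levels dA and dB every path of length <= dA + dB has
  // been detected, so reaching dA + dB = max_depth - 1 without a meeting
  // proves the distance exceeds max_depth - 1; the caller combines that
  // with its upper bound (status 1).
  while (dA + dB < max_depth - 1) {
    bool expandA = frontA.size() <= frontB.size();
    std::vector<Adj>& front = expandA ? frontA : frontB;
    std::unordered_map<std::string, int>& visSame = expandA ? visA : visB;
    std::unordered_map<std::string, int>& visOther = expandA ? visB : visA;
    int d = expandA ? dA : dB;
    std::vector<Adj> next;
    int best = INT_MAX;
    for (const Adj& t : front) {
      for_each_spr_neighbor(t, [&](const Adj& c) {
        tree_splits(c, ntips, s);
        std::string k = splits_raw_key(s);
        if (visSame.count(k)) return;
        visSame[k] = d + 1;
        auto it = visOther.find(k);
        if (it != visOther.end()) best = std::min(best, d + 1 + it->second);
        next.push_back(c);
      });
    }
    if (best != INT_MAX)
      return List::create(_["distance"] = best, _["status"] = 0);
    if ((int)(visA.size() + visB.size()) > max_states)
      return List::create(_["distance"] = -1, _["status"] = 2);
    front.swap(next);
    if (expandA) ++dA; else ++dB;
  }
  return List::create(_["distance"] = -1, _["status"] = 1);
}

// Greedy RF hill-climb upper bound on the SPR distance.  When no move
// strictly reduces RF the bound is completed constructively: every leaf
// outside a maximum agreement subtree can be relocated with one SPR move,
// so moves_so_far + (ntips - MAST) is always attainable.
// [[Rcpp::export(name = ".spr_greedy_cpp")]]
int spr_greedy_cpp(IntegerMatrix e1, IntegerMatrix e2, int ntips) {
  Adj cur = build_adj(e1, nullptr), target = build_adj(e2, nullptr);
  std::vector<uint64_t> st, s;
  tree_splits(target, ntips, st);
  std::vector<uint64_t> sc;
  tree_splits(cur, ntips, sc);
  int cur_rf = rf_from_splits(sc, st);
  int moves = 0;
  while (cur_rf != 0) {
    int best_rf = INT_MAX;
    Adj best;
    for_each_spr_neighbor(cur, [&](const Adj& c) {
      tree_splits(c, ntips, s);
      int r = rf_from_splits(s, st);
      if (r < best_rf) {
        best_rf = r;
        best = c;
      }
    });
    if (best_rf < cur_rf) {
      cur = best;
      cur_rf = best_rf;
      ++moves;
    } else {
      moves += ntips - mast_core(cur, target, ntips, nullptr);
      break;
    }
  }
  return moves;
}

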