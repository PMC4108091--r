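// Core tree machinery for Parsimony Analysis of Endemicity.
//
// Trees are unrooted binary trees over leaves 1..L, with leaf 1 reserved for
// the hypothetical all-absent outgroup area.  Internal nodes are numbered
// L+1 .. 2L-2.  A tree is an edge list (node pairs); topology identity is
// established through the sorted set of ingroup-side bipartition bitmasks
// read on the leaf-1-rooted view.
//
// Character states are bitmasks over {0,1}: 1 = {absent}, 2 = {present},
// 3 = {absent, present}.  The state matrix S is nchar x L (species x areas,
// with the outgroup column all 1).

#include <Rcpp.h>
#include <cstdint>
#include <array>
#include <vector>
#include <string>
#include <map>
#include <set>
#include <algorithm>
#include <climits>

using namespace Rcpp;

typedef std::array<int, 2> Edge;
typedef std::vector<Edge> EdgeList;

static int max_node(const EdgeList& E) {
  int nn = 0;
  for (const Edge& e : E) nn = std::max(nn, std::max(e[0], e[1]));
  return nn;
}

// Preorder walk rooted at leaf 1; fills preorder node list and parent array.
static void order_from_root(const EdgeList& E, std::vector<int>& order,
                            std::vector<int>& parent) {
  int nn = max_node(E);
  std::vector<std::vector<int>> adj(nn + 1);
  for (const Edge& e : E) {
    adj[e[0]].push_back(e[1]);
    adj[e[1]].push_back(e[0]);
  }
  order.clear();
  parent.assign(nn + 1, 0);
  std::vector<int> stk;
  stk.push_back(1);
  parent[1] = -1;
  while (!stk.empty()) {
    int u = stk.back();
    stk.pop_back();
    order.push_back(u);
    for (int v : adj[u])
      if (v != parent[u]) {
        parent[v] = u;
        stk.push_back(v);
      }
  }
}

// Fitch length: minimum number of 0<->1 changes summed over characters.
// Works for any subset of leaves present in E (leaf 1 must be present).
static int fitch_score(const EdgeList& E, const IntegerMatrix& S, int L) {
  int nchar = S.nrow();
  if (nchar == 0 || E.size() < 2) return 0;
  std::vector<int> order, parent;
  order_from_root(E, order, parent);
  int nn = max_node(E);
  std::vector<uint8_t> st(((size_t)nn + 1) * nchar, 0);
  std::vector<uint8_t> seen(nn + 1, 0);
  int changes = 0;
  int root_child = -1;
  // reversed preorder = children before parents
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    uint8_t* su = &st[(size_t)u * nchar];
    if (u <= L) {
      for (int c = 0; c < nchar; ++c) su[c] = (uint8_t)S(c, u - 1);
    }
    int p = parent[u];
    if (p == 1) root_child = u;
    if (p > 1) {
      uint8_t* sp = &st[(size_t)p * nchar];
      if (!seen[p]) {
        std::copy(su, su + nchar, sp);
        seen[p] = 1;
      } else {
        for (int c = 0; c < nchar; ++c) {
          uint8_t inter = sp[c] & su[c];
          if (inter) sp[c] = inter;
          else { sp[c] = sp[c] | su[c]; ++changes; }
        }
      }
    }
  }
  if (root_child > 0) {
    const uint8_t* sc = &st[(size_t)root_child * nchar];
    for (int c = 0; c < nchar; ++c)
      if (!(sc[c] & (uint8_t)S(c, 0))) ++changes;
  }
  return changes;
}

// Sorted ingroup bipartition masks of the internal edges; canonical topology id.
static std::string tree_key(const EdgeList& E, int L) {
  std::vector<int> order, parent;
  order_from_root(E, order, parent);
  int nn = max_node(E);
  int B = (L + 63) / 64;
  std::vector<std::vector<uint64_t>> below(nn + 1, std::vector<uint64_t>(B, 0));
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int u = order[i];
    if (u <= L) below[u][(u - 1) >> 6] |= (uint64_t)1 << ((u - 1) & 63);
    int p = parent[u];
    if (p > 0) for (int b = 0; b < B; ++b) below[p][b] |= below[u][b];
  }
  std::vector<std::vector<uint64_t>> splits;
  for (const Edge& e : E) {
    if (e[0] > L && e[1] > L) {
      int child = (parent[e[0]] == e[1]) ? e[0] : e[1];
      splits.push_back(below[child]);
    }
  }
  std::sort(splits.begin(), splits.end());
  std::string key;
  key.reserve(splits.size() * B * 8);
  for (const auto& s : splits)
    for (uint64_t w : s)
      for (int b = 0; b < 8; ++b) key.push_back((char)((w >> (8 * b)) & 0xFF));
  return key;
}

static std::string to_hex(const std::string& raw) {
  static const char* hexd = "0123456789abcdef";
  std::string out;
  out.reserve(raw.size() * 2);
  for (unsigned char c : raw) {
    out.push_back(hexd[c >> 4]);
    out.push_back(hexd[c & 15]);
  }
  return out;
}

static IntegerMatrix edges_to_matrix(const EdgeList& E) {
  IntegerMatrix m((int)E.size(), 2);
  for (int i = 0; i < (int)E.size(); ++i) {
    m(i, 0) = E[i][0];
    m(i, 1) = E[i][1];
  }
  return m;
}

static EdgeList matrix_to_edges(const IntegerMatrix& m) {
  EdgeList E;
  E.reserve(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) E.push_back({m(i, 0), m(i, 1)});
  return E;
}

// [[Rcpp::export]]
int cpp_fitch(IntegerMatrix edges, IntegerMatrix states, int L) {
  EdgeList E = matrix_to_edges(edges);
  return fitch_score(E, states, L);
}

// [[Rcpp::export]]
std::string cpp_tree_key(IntegerMatrix edges, int L) {
  EdgeList E = matrix_to_edges(edges);
  return to_hex(tree_key(E, L));
}

// ---------------------------------------------------------------------------
// exhaustive enumeration by sequential leaf insertion

struct ExCtx {
  const IntegerMatrix* S;
  int L;
  int best;
  long long examined;
  int max_store;
  std::vector<EdgeList> opt;
};

static void ex_rec(EdgeList& E, int k, ExCtx& ctx) {
  if (k > ctx.L) {
    ctx.examined++;
    int s = fitch_score(E, *(ctx.S), ctx.L);
    if (s < ctx.best) { ctx.best = s; ctx.opt.clear(); }
    if (s == ctx.best && (int)ctx.opt.size() < ctx.max_store)
      ctx.opt.push_back(E);
    return;
  }
  int w = ctx.L + (k - 2);
  int ne = (int)E.size();
  for (int i = 0; i < ne; ++i) {
    Edge old = E[i];
    E[i] = {old[0], w};
    E.push_back({w, old[1]});
    E.push_back({w, k});
    ex_rec(E, k + 1, ctx);
    E.pop_back();
    E.pop_back();
    E[i] = old;
  }
}

// [[Rcpp::export]]
List cpp_exhaustive(IntegerMatrix states, int L, int max_store = 10000) {
  if (L < 3) stop("need at least 3 leaves");
  if (L > 10) stop("exhaustive enumeration limited to 10 leaves");
  ExCtx ctx;
  ctx.S = &states;
  ctx.L = L;
  ctx.best = INT_MAX;
  ctx.examined = 0;
  ctx.max_store = max_store;
  EdgeList E = {{1, L + 1}, {2, L + 1}, {3, L + 1}};
  ex_rec(E, 4, ctx);
  List trees((int)ctx.opt.size());
  CharacterVector keys((int)ctx.opt.size());
  for (int i = 0; i < (int)ctx.opt.size(); ++i) {
    trees[i] = edges_to_matrix(ctx.opt[i]);
    keys[i] = to_hex(tree_key(ctx.opt[i], L));
  }
  return List::create(_["best_score"] = ctx.best,
                      _["n_examined"] = (double)ctx.examined,
                      _["trees"] = trees, _["keys"] = keys);
}

// ---------------------------------------------------------------------------
// stepwise addition (random addition sequence supplied from R)

// order: all L leaf ids; order[0..2] form the initial star.  Ties among
// equally good insertion edges are broken uniformly via R's RNG.
// [[Rcpp::export]]
List cpp_stepwise(IntegerMatrix states, IntegerVector order, int L) {
  if (order.size() != L) stop("order must list every leaf exactly once");
  if (L < 4) stop("need at least 4 leaves (3 areas plus outgroup)");
  EdgeList E = {{order[0], L + 1}, {order[1], L + 1}, {order[2], L + 1}};
  int next_internal = L + 2;
  for (int j = 3; j < L; ++j) {
    int k = order[j];
    int w = next_internal++;
    int ne = (int)E.size();
    int best = INT_MAX, chosen = -1, ties = 0;
    for (int i = 0; i < ne; ++i) {
      Edge old = E[i];
      E[i] = {old[0], w};
      E.push_back({w, old[1]});
      E.push_back({w, k});
      int s = fitch_score(E, states, L);
      E.pop_back();
      E.pop_back();
      E[i] = old;
      if (s < best) {
        best = s; chosen = i; ties = 1;
      } else if (s == best) {
        ++ties;
        if (unif_rand() < 1.0 / ties) chosen = i;
      }
    }
    Edge old = E[chosen];
    E[chosen] = {old[0], w};
    E.push_back({w, old[1]});
    E.push_back({w, k});
  }
  int s = fitch_score(E, states, L);
  return List::create(_["edges"] = edges_to_matrix(E), _["score"] = s);
}

// ---------------------------------------------------------------------------
// TBR hill climbing

// remove node of degree 2, joining its two neighbours
static void suppress(EdgeList& E, int node) {
  int i1 = -1, i2 = -1;
  for (int i = 0; i < (int)E.size(); ++i)
    if (E[i][0] == node || E[i][1] == node) {
      if (i1 < 0) i1 = i; else { i2 = i; break; }
    }
  if (i1 < 0 || i2 < 0) return;
  int a = (E[i1][0] == node) ? E[i1][1] : E[i1][0];
  int b = (E[i2][0] == node) ? E[i2][1] : E[i2][0];
  E[i1] = {a, b};
  E.erase(E.begin() + i2);
}

// All TBR neighbours of cur: bisect every edge, reconnect every edge pair of
// the two fragments (a single-leaf fragment reattaches by its leaf).
static void tbr_neighbours(const EdgeList& cur, int L,
                           std::vector<EdgeList>& out) {
  out.clear();
  int nn = max_node(cur);
  std::vector<std::vector<std::pair<int, int>>> adj(nn + 1);  // (nbr, edge idx)
  for (int i = 0; i < (int)cur.size(); ++i) {
    adj[cur[i][0]].push_back({cur[i][1], i});
    adj[cur[i][1]].push_back({cur[i][0], i});
  }
  for (int ci = 0; ci < (int)cur.size(); ++ci) {
    int u = cur[ci][0], v = cur[ci][1];
    // component of u avoiding edge ci
    std::vector<char> inA(nn + 1, 0);
    std::vector<int> stk;
    stk.push_back(u);
    inA[u] = 1;
    while (!stk.empty()) {
      int x = stk.back();
      stk.pop_back();
      for (auto& pr : adj[x])
        if (pr.second != ci && !inA[pr.first]) {
          inA[pr.first] = 1;
          stk.push_back(pr.first);
        }
    }
    EdgeList EA, EB;
    for (int j = 0; j < (int)cur.size(); ++j) {
      if (j == ci) continue;
      if (inA[cur[j][0]]) EA.push_back(cur[j]); else EB.push_back(cur[j]);
    }
    bool a_leaf = EA.empty(), b_leaf = EB.empty();
    if (!a_leaf && u > L) suppress(EA, u);
    if (!b_leaf && v > L) suppress(EB, v);
    int nA = a_leaf ? 1 : (int)EA.size();
    int nB = b_leaf ? 1 : (int)EB.size();
    for (int ia = 0; ia < nA; ++ia) {
      for (int ib = 0; ib < nB; ++ib) {
        EdgeList T = EA;
        int pa, pb;
        if (a_leaf) pa = u;
        else {
          Edge e = T[ia];
          T[ia] = {e[0], u};
          T.push_back({u, e[1]});
          pa = u;
        }
        size_t off = T.size();
        for (const Edge& e : EB) T.push_back(e);
        if (b_leaf) pb = v;
        else {
          Edge e = T[off + ib];
          T[off + ib] = {e[0], v};
          T.push_back({v, e[1]});
          pb = v;
        }
        T.push_back({pa, pb});
        out.push_back(std::move(T));
      }
    }
  }
}

// Hill-climb with strict-improvement acceptance; ties among best improving
// neighbours broken uniformly via R's RNG.  Retains up to `keep` distinct
// topologies tied at the best score encountered.
// [[Rcpp::export]]
List cpp_tbr(IntegerMatrix edges, IntegerMatrix states, int L, int keep = 100,
             int max_iter = 1000) {
  if (keep < 1) stop("keep must be >= 1");
  EdgeList cur = matrix_to_edges(edges);
  int curscore = fitch_score(cur, states, L);
  std::map<std::string, EdgeList> buffer;
  buffer[tree_key(cur, L)] = cur;
  int iterations = 0;
  std::vector<EdgeList> nb;
  for (int iter = 0; iter < max_iter; ++iter) {
    ++iterations;
    tbr_neighbours(cur, L, nb);
    int bestN = INT_MAX;
    std::vector<int> argmin;
    std::vector<int> equal_cur;
    for (int i = 0; i < (int)nb.size(); ++i) {
      int s = fitch_score(nb[i], states, L);
      if (s < bestN) { bestN = s; argmin.clear(); }
      if (s == bestN && (int)argmin.size() < keep) argmin.push_back(i);
      if (s == curscore && (int)equal_cur.size() < keep) equal_cur.push_back(i);
    }
    if (bestN < curscore) {
      int pick = argmin[(int)(unif_rand() * argmin.size()) % argmin.size()];
      cur = nb[pick];
      curscore = bestN;
      buffer.clear();
      buffer[tree_key(cur, L)] = cur;
      for (int i : argmin) {
        if ((int)buffer.size() >= keep) break;
        std::string k = tree_key(nb[i], L);
        if (!buffer.count(k)) buffer[k] = nb[i];
      }
    } else {
      for (int i : equal_cur) {
        if ((int)buffer.size() >= keep) break;
        std::string k = tree_key(nb[i], L);
        if (!buffer.count(k)) buffer[k] = nb[i];
      }
      break;
    }
  }
  List trees((int)buffer.size());
  CharacterVector keys((int)buffer.size());
  int i = 0;
  for (auto& kv : buffer) {
    keys[i] = to_hex(kv.first);
    trees[i] = edges_to_matrix(kv.second);
    ++i;
  }
  return List::create(_["best_score"] = curscore, _["trees"] = trees,
                      _["keys"] = keys, _["iterations"] = iterations);
}

// [[Rcpp::export]]
List cpp_tbr_neighbourhood(IntegerMatrix edges, int L) {
  EdgeList cur = matrix_to_edges(edges);
  std::vector<EdgeList> nb;
  tbr_neighbours(cur, L, nb);
  List out((int)nb.size());
  for (int i = 0; i < (int)nb.size(); ++i) out[i] = edges_to_matrix(nb[i]);
  return out;
}
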