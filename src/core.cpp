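#include <Rcpp.h>
#include <cstdint>
#include <queue>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// 32-bit FNV-1a; stable across platforms, used to pre-hash shingle strings
static inline uint32_t fnv1a32(const char *s) {
  uint32_t h = 2166136261u;
  for (; *s; ++s) {
    h ^= (uint8_t)(*s);
    h *= 16777619u;
  }
  return h;
}

// [[Rcpp::export]]
NumericVector hash_strings_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (double)fnv1a32(CHAR(STRING_ELT(x, i)));
  return out;
}

struct Graph {
  int n;
  std::vector<std::vector<int>> adj;   // 0-based neighbors
  std::vector<std::vector<int>> bord;  // bond order parallel to adj
};

static Graph make_graph(int n, const IntegerVector &from, const IntegerVector &to,
                        const IntegerVector &order) {
  Graph g;
  g.n = n;
  g.adj.assign(n, {});
  g.bord.assign(n, {});
  for (int k = 0; k < from.size(); ++k) {
    int i = from[k] - 1, j = to[k] - 1, o = order[k];
    g.adj[i].push_back(j); g.bord[i].push_back(o);
    g.adj[j].push_back(i); g.bord[j].push_back(o);
  }
  return g;
}

static void bfs(const Graph &g, int src, std::vector<int> &dist) {
  dist.assign(g.n, -1);
  dist[src] = 0;
  std::queue<int> q;
  q.push(src);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int w : g.adj[v])
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
  }
}

// topological distance matrix in bonds; -1 marks disconnected pairs
// [[Rcpp::export]]
IntegerMatrix pair_distances_cpp(int n, IntegerVector from, IntegerVector to,
                                 IntegerVector order) {
  Graph g = make_graph(n, from, to, order);
  IntegerMatrix D(n, n);
  std::vector<int> dist;
  for (int i = 0; i < n; ++i) {
    bfs(g, i, dist);
    for (int j = 0; j < n; ++j) D(i, j) = dist[j];
  }
  return D;
}

static const char *bond_tok(int o) {
  switch (o) {
    case 2: return "=";
    case 3: return "#";
    default: return "";
  }
}

// serializer state for one rooted environment
struct EnvWriter {
  const Graph *g;
  int root;
  std::vector<bool> inset, visited;
  std::vector<std::string> sym;
  // discovered DFS tree: ordered children with bond order
  std::vector<std::vector<std::pair<int, int>>> children;
  // ring-closure tokens to emit at each atom (digit already formatted with bond symbol)
  std::vector<std::vector<std::string>> rings;
  int next_digit = 1;

  std::string digit_tok(int d) {
    if (d < 10) return std::string(1, '0' + d);
    return "%" + std::to_string(d);
  }

  void discover(int v, int parent) {
    visited[v] = true;
    const auto &nb = g->adj[v];
    const auto &bo = g->bord[v];
    for (size_t k = 0; k < nb.size(); ++k) {
      int w = nb[k];
      if (!inset[w] || w == parent) continue;
      if (visited[w]) continue;  // back edges handled below to avoid duplicates
      children[v].push_back({w, bo[k]});
      discover(w, v);
    }
  }

  // second pass over edges: any in-set edge not in the DFS tree is a ring closure
  void find_rings() {
    std::set<std::pair<int, int>> te;  // tree edges as ordered pairs
    for (int v = 0; v < g->n; ++v)
      for (auto &c : children[v]) {
        te.insert({std::min(v, c.first), std::max(v, c.first)});
      }
    std::set<std::pair<int, int>> done;
    for (int v = 0; v < g->n; ++v) {
      if (!inset[v]) continue;
      const auto &nb = g->adj[v];
      const auto &bo = g->bord[v];
      for (size_t k = 0; k < nb.size(); ++k) {
        int w = nb[k];
        if (!inset[w]) continue;
        std::pair<int, int> e{std::min(v, w), std::max(v, w)};
        if (te.count(e) || done.count(e)) continue;
        done.insert(e);
        std::string d = digit_tok(next_digit++);
        std::string tok = std::string(bond_tok(bo[k])) + d;
        rings[e.first].push_back(tok);
        rings[e.second].push_back(tok);
      }
    }
  }

  std::string atom_tok(int v) {
    const std::string &s = sym[v];
    if (v == root) return "[99" + s + "]";
    if (s.size() > 1 && s != "Cl" && s != "Br") return "[" + s + "]";
    return s;
  }

  std::string serialize(int v) {
    std::string out = atom_tok(v);
    for (const auto &r : rings[v]) out += r;
    const auto &ch = children[v];
    for (size_t k = 0; k < ch.size(); ++k) {
      std::string sub = std::string(bond_tok(ch[k].second)) + serialize(ch[k].first);
      if (k + 1 < ch.size())
        out += "(" + sub + ")";
      else
        out += sub;
    }
    return out;
  }
};

// naive (non-canonical) rooted SMILES of the radius-r environment of every atom;
// the caller canonicalizes the unique strings through OpenBabel
// [[Rcpp::export]]
CharacterVector env_smiles_cpp(int n, CharacterVector symbols, IntegerVector from,
                               IntegerVector to, IntegerVector order, int radius) {
  Graph g = make_graph(n, from, to, order);
  std::vector<std::string> sym(n);
  for (int i = 0; i < n; ++i) sym[i] = CHAR(STRING_ELT(symbols, i));
  CharacterVector out(n);
  std::vector<int> dist;
  for (int rt = 0; rt < n; ++rt) {
    bfs(g, rt, dist);
    EnvWriter ew;
    ew.g = &g;
    ew.root = rt;
    ew.sym = sym;
    ew.inset.assign(n, false);
    for (int i = 0; i < n; ++i)
      if (dist[i] >= 0 && dist[i] <= radius) ew.inset[i] = true;
    ew.visited.assign(n, false);
    ew.children.assign(n, {});
    ew.rings.assign(n, {});
    ew.discover(rt, -1);
    ew.find_rings();
    out[rt] = ew.serialize(rt);
  }
  return out;
}

// build the deduplicated shingle set "<envA>|<dist>|<envB>" for one molecule,
// given canonical env strings per atom per radius and the distance matrix
// [[Rcpp::export]]
CharacterVector shingle_set_cpp(CharacterMatrix envs, IntegerMatrix D) {
  int n = envs.nrow(), nr = envs.ncol();
  std::set<std::string> shingles;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = D(i, j);
      if (d < 0) continue;  // disconnected fragments: no topological distance
      std::string ds = std::to_string(d);
      for (int r = 0; r < nr; ++r) {
        std::string a = CHAR(envs(i, r)), b = CHAR(envs(j, r));
        if (b < a) std::swap(a, b);
        shingles.insert(a + "|" + ds + "|" + b);
      }
    }
  }
  return CharacterVector(shingles.begin(), shingles.end());
}

static const uint64_t MERSENNE31 = 2147483647ull;  // 2^31 - 1

// MinHash of pre-hashed shingle sets under d universal hash functions
// h_k(x) = (a_k * x + b_k) mod (2^31 - 1)
// [[Rcpp::export]]
IntegerMatrix minhash_cpp(List shingle_hashes, NumericVector a, NumericVector b) {
  int d = a.size();
  int n = shingle_hashes.size();
  IntegerMatrix out(n, d);
  std::vector<uint64_t> A(d), B(d);
  for (int k = 0; k < d; ++k) {
    A[k] = (uint64_t)a[k];
    B[k] = (uint64_t)b[k];
  }
  std::vector<uint64_t> mins(d);
  for (int m = 0; m < n; ++m) {
    NumericVector hv = shingle_hashes[m];
    if (hv.size() == 0) stop("empty shingle set");
    std::fill(mins.begin(), mins.end(), UINT64_MAX);
    for (R_xlen_t s = 0; s < hv.size(); ++s) {
      uint64_t x = ((uint64_t)hv[s]) % MERSENNE31;
      for (int k = 0; k < d; ++k) {
        uint64_t h = (A[k] * x + B[k]) % MERSENNE31;
        if (h < mins[k]) mins[k] = h;
      }
    }
    for (int k = 0; k < d; ++k) out(m, k) = (int)mins[k];
  }
  return out;
}

// MAP4 custom kernel: fraction of positions with identical MinHash values
// [[Rcpp::export]]
NumericMatrix match_fraction_cpp(IntegerMatrix X, IntegerMatrix Y) {
  int nx = X.nrow(), ny = Y.nrow(), d = X.ncol();
  if (Y.ncol() != d) stop("fingerprint dimensionality mismatch");
  NumericMatrix K(nx, ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      int m = 0;
      for (int k = 0; k < d; ++k)
        if (X(i, k) == Y(j, k)) ++m;
      K(i, j) = (double)m / d;
    }
  }
  return K;
}

// common MinHash-prefix depth between query rows and index rows for one
// LSH tree (columns = the tree's hash positions in order)
// [[Rcpp::export]]
IntegerMatrix prefix_depths_cpp(IntegerMatrix keys, IntegerMatrix queries) {
  int n = keys.nrow(), L = keys.ncol(), m = queries.nrow();
  if (queries.ncol() != L) stop("key length mismatch");
  IntegerMatrix out(m, n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      int depth = 0;
      while (depth < L && keys(i, depth) == queries(q, depth)) ++depth;
      out(q, i) = depth;
    }
  }
  return out;
}
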