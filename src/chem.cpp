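// Molecular fragment enumeration and hashing.
//
// Hot loops of the fingerprint module: simple-path enumeration (linear
// fragments of up to 7 atoms), circular-sphere enumeration (induced
// neighborhoods of radius 1..5 with a canonical serialization), and the
// FNV-1a 64-bit hash that maps canonical fragment strings to bit positions.
// Canonical labeling uses iterative neighborhood refinement on
// (symbol, degree) colors with individualization backtracking, so fragment
// strings are invariant under graph isomorphism.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_hash_bits(CharacterVector strings, int nbits) {
  const uint64_t offset = 14695981039346656037ULL;
  const uint64_t prime = 1099511628211ULL;
  IntegerVector out(strings.size());
  for (R_xlen_t s = 0; s < strings.size(); ++s) {
    const char *p = CHAR(STRING_ELT(strings, s));
    uint64_t h = offset;
    for (; *p; ++p) {
      h ^= static_cast<uint64_t>(static_cast<unsigned char>(*p));
      h *= prime;
    }
    out[s] = static_cast<int>(h % static_cast<uint64_t>(nbits));
  }
  return out;
}

struct Graph {
  int n;
  std::vector<std::string> sym;                 // atom symbol (case = aromaticity)
  std::vector<std::vector<int>> nbr;            // adjacency
  std::vector<std::vector<char>> nbr_bond;      // bond symbol per adjacency entry
};

static Graph build_graph(int n_atoms, CharacterVector sym, IntegerVector bi,
                         IntegerVector bj, CharacterVector border) {
  Graph g;
  g.n = n_atoms;
  g.sym.resize(n_atoms);
  for (int i = 0; i < n_atoms; ++i) g.sym[i] = as<std::string>(sym[i]);
  g.nbr.assign(n_atoms, {});
  g.nbr_bond.assign(n_atoms, {});
  for (R_xlen_t e = 0; e < bi.size(); ++e) {
    int a = bi[e] - 1, b = bj[e] - 1;
    char o = CHAR(STRING_ELT(border, e))[0];
    g.nbr[a].push_back(b); g.nbr_bond[a].push_back(o);
    g.nbr[b].push_back(a); g.nbr_bond[b].push_back(o);
  }
  return g;
}

// ---- path enumeration -----------------------------------------------------

static void path_string(const Graph &g, const std::vector<int> &path,
                        const std::vector<char> &bonds, std::string &fwd,
                        std::string &rev) {
  fwd.clear(); rev.clear();
  for (size_t k = 0; k < path.size(); ++k) {
    if (k) fwd += bonds[k - 1];
    fwd += g.sym[path[k]];
  }
  for (size_t k = path.size(); k-- > 0;) {
    if (k + 1 < path.size()) rev += bonds[k];
    rev += g.sym[path[k]];
  }
}

static void dfs_paths(const Graph &g, std::vector<int> &path,
                      std::vector<char> &bonds, std::vector<bool> &used,
                      int max_atoms, std::vector<std::string> &out) {
  int last = path.back();
  if (path.size() >= 2 && path[0] < last) {
    std::string fwd, rev;
    path_string(g, path, bonds, fwd, rev);
    out.push_back(std::min(fwd, rev));
  }
  if ((int)path.size() == max_atoms) return;
  for (size_t k = 0; k < g.nbr[last].size(); ++k) {
    int v = g.nbr[last][k];
    if (used[v]) continue;
    used[v] = true;
    path.push_back(v);
    bonds.push_back(g.nbr_bond[last][k]);
    dfs_paths(g, path, bonds, used, max_atoms, out);
    bonds.pop_back();
    path.pop_back();
    used[v] = false;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate_paths(int n_atoms, CharacterVector sym,
                                    IntegerVector bi, IntegerVector bj,
                                    CharacterVector border, int max_atoms) {
  Graph g = build_graph(n_atoms, sym, bi, bj, border);
  std::vector<std::string> out;
  for (int a = 0; a < g.n; ++a) out.push_back(g.sym[a]);  // 1-atom paths
  std::vector<int> path;
  std::vector<char> bonds;
  std::vector<bool> used(g.n, false);
  for (int a = 0; a < g.n; ++a) {
    path.assign(1, a);
    bonds.clear();
    std::fill(used.begin(), used.end(), false);
    used[a] = true;
    dfs_paths(g, path, bonds, used, max_atoms, out);
  }
  return wrap(out);
}

// ---- canonical serialization of an induced subgraph -----------------------

struct SubGraph {
  int n;
  std::vector<std::string> sym;   // includes center marker where applicable
  std::vector<std::vector<std::pair<int, char>>> adj; // (local nbr, bond)
};

static std::string serialize(const SubGraph &s, const std::vector<int> &order) {
  // order[v] = canonical position of local node v
  std::vector<int> at(s.n);          // at[pos] = local node
  for (int v = 0; v < s.n; ++v) at[order[v]] = v;
  std::string str = std::to_string(s.n) + ":";
  for (int p = 0; p < s.n; ++p) {
    if (p) str += ';';
    str += s.sym[at[p]];
  }
  std::vector<std::string> edges;
  for (int v = 0; v < s.n; ++v) {
    for (auto &pr : s.adj[v]) {
      if (v < pr.first) {
        int a = order[v], b = order[pr.first];
        if (a > b) std::swap(a, b);
        edges.push_back(std::to_string(a) + pr.second + std::to_string(b));
      }
    }
  }
  std::sort(edges.begin(), edges.end());
  str += '|';
  for (size_t e = 0; e < edges.size(); ++e) {
    if (e) str += ',';
    str += edges[e];
  }
  return str;
}

// zero-padded label so lexicographic key order equals numeric label order
// (unpadded labels can permute classes forever once >= 10 classes exist)
static std::string pad(int x) {
  std::string s = std::to_string(x);
  while (s.size() < 4) s = "0" + s;
  return s;
}

// one round of color refinement; colors become ranks of (color, nbr multiset)
static bool refine(const SubGraph &s, std::vector<int> &color) {
  std::vector<std::string> key(s.n);
  for (int v = 0; v < s.n; ++v) {
    std::vector<std::string> nb;
    for (auto &pr : s.adj[v])
      nb.push_back(std::string(1, pr.second) + pad(color[pr.first]));
    std::sort(nb.begin(), nb.end());
    key[v] = pad(color[v]) + "#";
    for (auto &x : nb) key[v] += x + "!";
  }
  std::vector<std::string> uniq(key);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  std::vector<int> newcol(s.n);
  for (int v = 0; v < s.n; ++v)
    newcol[v] = std::lower_bound(uniq.begin(), uniq.end(), key[v]) - uniq.begin();
  bool changed = (newcol != color);
  color = newcol;
  return changed;
}

static void canon_rec(const SubGraph &s, std::vector<int> color,
                      std::string &best, bool &have_best, int depth) {
  while (refine(s, color)) {}
  // find smallest non-singleton color class
  int target = -1;
  std::vector<int> members;
  for (int c = 0;; ++c) {
    members.clear();
    for (int v = 0; v < s.n; ++v) if (color[v] == c) members.push_back(v);
    if (members.empty()) { target = -1; break; }
    if (members.size() > 1) { target = c; break; }
  }
  if (target < 0) {
    // discrete: color is a permutation 0..n-1
    std::string str = serialize(s, color);
    if (!have_best || str < best) { best = str; have_best = true; }
    return;
  }
  if (depth > 24) {  // safety valve; fragments are tiny in practice
    std::string str;
    std::vector<std::pair<int, int>> byc(s.n);
    for (int v = 0; v < s.n; ++v) byc[v] = {color[v], v};
    std::sort(byc.begin(), byc.end());
    std::vector<int> order(s.n);
    for (int p = 0; p < s.n; ++p) order[byc[p].second] = p;
    str = serialize(s, order);
    if (!have_best || str < best) { best = str; have_best = true; }
    return;
  }
  for (int v : members) {
    std::vector<int> c2(color);
    for (int u = 0; u < s.n; ++u) if (c2[u] >= c2[v] && u != v) c2[u] += 1;
    // v keeps the old color value; everyone at or above is shifted: v is now
    // the unique holder of its color.
    canon_rec(s, c2, best, have_best, depth + 1);
  }
}

static std::string canonical_fragment(const SubGraph &s) {
  std::vector<std::string> uniq(s.sym);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  std::vector<int> color(s.n);
  for (int v = 0; v < s.n; ++v) {
    color[v] = std::lower_bound(uniq.begin(), uniq.end(), s.sym[v]) - uniq.begin();
  }
  std::string best;
  bool have = false;
  canon_rec(s, color, best, have, 0);
  return best;
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate_spheres(int n_atoms, CharacterVector sym,
                                      IntegerVector bi, IntegerVector bj,
                                      CharacterVector border, int max_layers) {
  Graph g = build_graph(n_atoms, sym, bi, bj, border);
  std::vector<std::string> out;
  std::vector<int> dist(g.n);
  for (int center = 0; center < g.n; ++center) {
    // BFS distances from the center
    std::fill(dist.begin(), dist.end(), -1);
    std::vector<int> queue{center};
    dist[center] = 0;
    for (size_t h = 0; h < queue.size(); ++h) {
      int v = queue[h];
      for (int w : g.nbr[v]) if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        queue.push_back(w);
      }
    }
    for (int r = 1; r <= max_layers; ++r) {
      std::vector<int> nodes;
      for (int v = 0; v < g.n; ++v) if (dist[v] >= 0 && dist[v] <= r)
        nodes.push_back(v);
      std::vector<int> local(g.n, -1);
      for (size_t k = 0; k < nodes.size(); ++k) local[nodes[k]] = (int)k;
      SubGraph s;
      s.n = (int)nodes.size();
      s.sym.resize(s.n);
      s.adj.assign(s.n, {});
      for (int k = 0; k < s.n; ++k) {
        int v = nodes[k];
        s.sym[k] = g.sym[v] + (v == center ? "*" : "");
        for (size_t e = 0; e < g.nbr[v].size(); ++e) {
          int w = g.nbr[v][e];
          if (local[w] >= 0)
            s.adj[k].push_back({local[w], g.nbr_bond[v][e]});
        }
      }
      // no radius prefix: identical neighborhoods at different radii
      // collapse to one distinct fragment string
      out.push_back(canonical_fragment(s));
    }
  }
  return wrap(out);
}
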