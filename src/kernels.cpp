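#include <Rcpp.h>
#include <random>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Edges are passed as an m x 2 IntegerMatrix of 1-based vertex ids and kept
// 0-based internally. The edge set supports O(1) membership (hash on a packed
// 64-bit key) and O(1) uniform sampling (flat vector + index draw), the two
// operations the switch chain needs.

static inline uint64_t edge_key(int u, int v, int n) {
  int a = u < v ? u : v, b = u < v ? v : u;
  return (uint64_t)a * (uint64_t)n + (uint64_t)b;
}

struct EdgeSet {
  std::vector<std::pair<int,int> > edges;  // stored with first < second
  std::unordered_set<uint64_t> keys;
  int n;

  EdgeSet(const IntegerMatrix& em, int n_) : n(n_) {
    int m = em.nrow();
    edges.reserve(m);
    keys.reserve((size_t)m * 2);
    for (int i = 0; i < m; ++i) {
      int u = em(i, 0) - 1, v = em(i, 1) - 1;
      if (u > v) std::swap(u, v);
      edges.push_back(std::make_pair(u, v));
      keys.insert(edge_key(u, v, n));
    }
  }
  bool has(int u, int v) const {
    return keys.count(edge_key(u, v, n)) > 0;
  }
  void replace(int idx, int u, int v) {
    keys.erase(edge_key(edges[idx].first, edges[idx].second, n));
    if (u > v) std::swap(u, v);
    edges[idx] = std::make_pair(u, v);
    keys.insert(edge_key(u, v, n));
  }
  IntegerMatrix to_matrix() const {
    IntegerMatrix out(edges.size(), 2);
    for (size_t i = 0; i < edges.size(); ++i) {
      out(i, 0) = edges[i].first + 1;
      out(i, 1) = edges[i].second + 1;
    }
    return out;
  }
};

// One switch proposal: edges {u,v},{y,z} -> {u,z},{y,v} after a fair coin on
// the pairing orientation. Rejected whenever a proposed edge would be a
// self-loop or is already present (so re-creating an existing incidence is a
// rejection even when the graph would stay unchanged).
static bool try_switch(EdgeSet& es, std::mt19937& rng, int i, int j) {
  int u = es.edges[i].first, v = es.edges[i].second;
  int y = es.edges[j].first, z = es.edges[j].second;
  if (rng() & 1u) std::swap(y, z);
  // proposal: {u,z}, {y,v}
  if (u == z || y == v) return false;
  if (es.has(u, z) || es.has(y, v)) return false;
  es.replace(i, u, z);
  es.replace(j, y, v);
  return true;
}

// [[Rcpp::export]]
List cpp_switch_randomize(IntegerMatrix em, int n, double attempts, int seed) {
  EdgeSet es(em, n);
  int m = es.edges.size();
  long long total = (long long)attempts, applied = 0;
  if (m >= 2) {
    std::mt19937 rng((uint32_t)seed);
    std::uniform_int_distribution<int> pick(0, m - 1);
    for (long long t = 0; t < total; ++t) {
      int i = pick(rng), j = pick(rng);
      while (j == i) j = pick(rng);
      if (try_switch(es, rng, i, j)) ++applied;
    }
  } else {
    total = 0;
  }
  return List::create(_["edges"] = es.to_matrix(),
                      _["attempts"] = (double)total,
                      _["applied"] = (double)applied);
}

// Havel-Hakimi: repeatedly satisfy the largest remaining degree by connecting
// it to the next-largest ones. Succeeds iff the sequence is graphical.
// [[Rcpp::export]]
IntegerMatrix cpp_havel_hakimi(IntegerVector degrees) {
  int n = degrees.size();
  std::vector<std::pair<int,int> > rem;  // (residual degree, node)
  long long dsum = 0;
  for (int i = 0; i < n; ++i) {
    if (degrees[i] < 0) stop("negative degree");
    dsum += degrees[i];
    if (degrees[i] > 0) rem.push_back(std::make_pair(degrees[i], i));
  }
  if (dsum % 2 != 0) stop("degree sum is odd");
  std::vector<std::pair<int,int> > edges;
  edges.reserve(dsum / 2);
  while (!rem.empty()) {
    std::sort(rem.begin(), rem.end(),
              [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
                return a.first > b.first ||
                       (a.first == b.first && a.second < b.second);
              });
    int d = rem[0].first, u = rem[0].second;
    if (d > (int)rem.size() - 1)
      stop("degree sequence is not graphical");
    rem[0].first = 0;
    for (int k = 1; k <= d; ++k) {
      edges.push_back(std::make_pair(u, rem[k].second));
      rem[k].first -= 1;
    }
    rem.erase(std::remove_if(rem.begin(), rem.end(),
                             [](const std::pair<int,int>& p) {
                               return p.first == 0;
                             }),
              rem.end());
  }
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = std::min(edges[i].first, edges[i].second) + 1;
    out(i, 1) = std::max(edges[i].first, edges[i].second) + 1;
  }
  return out;
}

// Forbidden-edge rewiring: an edge is forbidden when both endpoints share a
// community label. Each sweep pairs every currently forbidden edge with a
// uniformly drawn partner and applies the switch (either orientation) only if
// the result is simple and strictly decreases the forbidden count among the
// four edges involved.
// [[Rcpp::export]]
List cpp_rewire_forbidden(IntegerMatrix em, int n, IntegerVector comm,
                          int max_sweeps, int seed) {
  EdgeSet es(em, n);
  int m = es.edges.size();
  std::mt19937 rng((uint32_t)seed);
  auto forb = [&](int u, int v) { return comm[u] == comm[v]; };
  int sweeps = 0;
  long long residual = 0;
  for (; sweeps < max_sweeps; ++sweeps) {
    std::vector<int> bad;
    for (int i = 0; i < m; ++i)
      if (forb(es.edges[i].first, es.edges[i].second)) bad.push_back(i);
    residual = bad.size();
    if (residual == 0 || m < 2) break;
    std::shuffle(bad.begin(), bad.end(), rng);
    std::uniform_int_distribution<int> pick(0, m - 1);
    bool any = false;
    for (size_t b = 0; b < bad.size(); ++b) {
      int i = bad[b];
      int u = es.edges[i].first, v = es.edges[i].second;
      if (!forb(u, v)) continue;  // already fixed by an earlier switch
      int j = pick(rng);
      while (j == i) j = pick(rng);
      int y = es.edges[j].first, z = es.edges[j].second;
      int before = (forb(u, v) ? 1 : 0) + (forb(y, z) ? 1 : 0);
      int first = rng() & 1u;
      for (int o = 0; o < 2; ++o) {
        int yy = y, zz = z;
        if ((o ^ first) & 1) std::swap(yy, zz);
        // proposal {u,zz}, {yy,v}
        if (u == zz || yy == v) continue;
        if (es.has(u, zz) || es.has(yy, v)) continue;
        int after = (forb(u, zz) ? 1 : 0) + (forb(yy, v) ? 1 : 0);
        if (after >= before) continue;
        es.replace(i, u, zz);
        es.replace(j, yy, v);
        any = true;
        break;
      }
    }
    if (!any && residual > 0) {
      // count once more, then keep sweeping only if something can still move
      long long still = 0;
      for (int i = 0; i < m; ++i)
        if (forb(es.edges[i].first, es.edges[i].second)) ++still;
      residual = still;
      if (still == 0) break;
    }
  }
  // final residual count
  residual = 0;
  for (int i = 0; i < m; ++i)
    if (forb(es.edges[i].first, es.edges[i].second)) ++residual;
  return List::create(_["edges"] = es.to_matrix(),
                      _["residual"] = (double)residual,
                      _["sweeps"] = sweeps);
}

// R-MAT sampler: recursive quadrant descent on a 2^s x 2^s adjacency grid
// with probabilities (a,b,c,d); self-loops, duplicates and edges touching a
// deleted node are ignored; sampling stops once the average degree over the
// surviving nodes reaches `target_avg` (checked every `check_every` accepted
// edges), or after `max_draws` proposals.
// [[Rcpp::export]]
List cpp_rmat_sample(int s, double a, double b, double c, double d,
                     IntegerVector keep, double target_avg, int check_every,
                     double max_draws, int seed) {
  int64_t N = (int64_t)1 << s;
  int n_keep = keep.size();
  std::vector<char> kept((size_t)N, 0);
  for (int i = 0; i < n_keep; ++i) kept[keep[i] - 1] = 1;
  std::mt19937 rng((uint32_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double ab = a + b, abc = a + b + c;
  std::unordered_set<uint64_t> seen;
  std::vector<std::pair<int64_t,int64_t> > edges;
  long long accepted = 0, draws = 0;
  while (draws < (long long)max_draws) {
    ++draws;
    int64_t row = 0, col = 0;
    for (int level = 0; level < s; ++level) {
      double r = unif(rng);
      row <<= 1; col <<= 1;
      if (r < a) {
      } else if (r < ab) {
        col |= 1;
      } else if (r < abc) {
        row |= 1;
      } else {
        row |= 1; col |= 1;
      }
    }
    if (row == col) continue;
    if (!kept[(size_t)row] || !kept[(size_t)col]) continue;
    int64_t lo = std::min(row, col), hi = std::max(row, col);
    uint64_t key = (uint64_t)lo * (uint64_t)N + (uint64_t)hi;
    if (seen.count(key)) continue;
    seen.insert(key);
    edges.push_back(std::make_pair(lo, hi));
    ++accepted;
    if (accepted % check_every == 0 &&
        2.0 * accepted / n_keep >= target_avg)
      break;
  }
  IntegerMatrix out(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = (int)edges[i].first + 1;
    out(i, 1) = (int)edges[i].second + 1;
  }
  return List::create(_["edges"] = out, _["draws"] = (double)draws);
}
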