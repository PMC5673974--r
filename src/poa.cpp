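// Partial-order alignment (POA) for amplicon read polishing.
//
// Greedy sequence-to-graph global alignment with linear gap costs: the first
// read seeds a linear chain; each subsequent read is aligned to the current
// DAG by dynamic programming over a topological order, matched bases fuse
// into existing nodes, mismatches and insertions add nodes, and edge weights
// count read traversals. The consensus is the heaviest start-to-end path.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <string>
#include <limits>
#include <climits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Graph {
  std::vector<char> base;
  std::vector<int> support;
  std::vector<int> start_count, end_count;
  // adjacency: parallel vectors of (to, weight) per node
  std::vector<std::vector<std::pair<int,int> > > out;
  std::vector<std::vector<int> > in; // predecessor ids

  int add_node(char b) {
    base.push_back(b);
    support.push_back(1);
    start_count.push_back(0);
    end_count.push_back(0);
    out.push_back({});
    in.push_back({});
    return (int)base.size() - 1;
  }
  void add_edge(int u, int v) {
    for (auto &e : out[u]) {
      if (e.first == v) { e.second++; return; }
    }
    out[u].push_back(std::make_pair(v, 1));
    in[v].push_back(u);
  }
  size_t n() const { return base.size(); }

  std::vector<int> topo_order() const {
    std::vector<int> indeg(n(), 0);
    for (size_t u = 0; u < n(); ++u)
      for (auto &e : out[u]) indeg[e.first]++;
    std::deque<int> q;
    for (size_t u = 0; u < n(); ++u) if (indeg[u] == 0) q.push_back((int)u);
    std::vector<int> order;
    order.reserve(n());
    while (!q.empty()) {
      int u = q.front(); q.pop_front();
      order.push_back(u);
      for (auto &e : out[u]) if (--indeg[e.first] == 0) q.push_back(e.first);
    }
    if (order.size() != n()) stop("POA graph contains a cycle");
    return order;
  }
};

const int NEG = std::numeric_limits<int>::min() / 4;

// Global alignment of `read` to the graph; applies the read to the graph and
// returns the alignment score.
int align_and_insert(Graph &g, const std::string &read,
                     int match, int mismatch, int gap) {
  const int L = (int)read.size();
  if (g.n() == 0) {
    int prev = -1;
    for (int i = 0; i < L; ++i) {
      int v = g.add_node(read[i]);
      if (prev >= 0) g.add_edge(prev, v);
      prev = v;
    }
    g.start_count[0] += 1;
    g.end_count[g.n() - 1] += 1;
    return match * L;
  }

  std::vector<int> order = g.topo_order();
  const int N = (int)g.n();
  std::vector<int> rank(N);
  for (int k = 0; k < N; ++k) rank[order[k]] = k;

  // DP tables over (read prefix i = 0..L) x (node v), plus the virtual-source
  // column V[i] (no node consumed yet).
  std::vector<int> S((size_t)(L + 1) * N, NEG);
  std::vector<int> Pred((size_t)(L + 1) * N, -2);   // -1 = virtual source
  std::vector<unsigned char> Move((size_t)(L + 1) * N, 0); // 0 diag, 1 del, 2 ins
  std::vector<int> V(L + 1);
  for (int i = 0; i <= L; ++i) V[i] = gap * i;

  // column-major per node: consecutive read positions are contiguous
  auto idx = [L](int i, int v) { return (size_t)v * (L + 1) + i; };

  for (int k = 0; k < N; ++k) {
    int v = order[k];
    bool is_start = g.start_count[v] > 0 || g.in[v].empty();
    for (int i = 0; i <= L; ++i) {
      int best = NEG, bp = -2; unsigned char mv = 0;
      // diagonal and deletion from each predecessor (or the virtual source)
      if (is_start) {
        if (i >= 1) {
          int sc = V[i - 1] + (read[i - 1] == g.base[v] ? match : mismatch);
          if (sc > best) { best = sc; bp = -1; mv = 0; }
        }
        int sc = V[i] + gap;
        if (sc > best) { best = sc; bp = -1; mv = 1; }
      }
      for (int u : g.in[v]) {
        if (i >= 1) {
          int sc = S[idx(i - 1, u)] + (read[i - 1] == g.base[v] ? match : mismatch);
          if (sc > best) { best = sc; bp = u; mv = 0; }
        }
        int sc = S[idx(i, u)] + gap;
        if (sc > best) { best = sc; bp = u; mv = 1; }
      }
      // insertion: consume a read base, stay on v
      if (i >= 1) {
        int sc = S[idx(i - 1, v)] + gap;
        if (sc > best) { best = sc; bp = v; mv = 2; }
      }
      S[idx(i, v)] = best;
      Pred[idx(i, v)] = bp;
      Move[idx(i, v)] = mv;
    }
  }

  // alignment must end at a node where some read ends (or a graph sink)
  int best_end = -1, best_score = NEG;
  for (int v = 0; v < N; ++v) {
    if (g.end_count[v] == 0 && !g.out[v].empty()) continue;
    if (S[idx(L, v)] > best_score) { best_score = S[idx(L, v)]; best_end = v; }
  }
  if (best_end < 0) stop("POA alignment failed");

  // traceback: collect (read_pos, node, move) then apply to the graph
  struct Step { int i, v; unsigned char mv; };
  std::vector<Step> steps;
  int i = L, v = best_end;
  while (true) {
    unsigned char mv = Move[idx(i, v)];
    int p = Pred[idx(i, v)];
    steps.push_back({i, v, mv});
    if (mv == 0) {        // diagonal: consumed read[i-1] at v
      i -= 1;
      if (p == -1) break; // entered the graph here; remaining prefix is leading
      v = p;
    } else if (mv == 1) { // deletion: consumed v without a read base
      if (p == -1) break;
      v = p;
    } else {              // insertion: consumed read[i-1], stayed on v
      i -= 1;
    }
  }
  std::reverse(steps.begin(), steps.end());

  // build the read's node path
  std::vector<int> path;
  path.reserve(L);
  for (auto &st : steps) {
    if (st.mv == 0) { // diagonal: read base st.i-1 against node st.v
      char b = read[st.i - 1];
      if (g.base[st.v] == b) { g.support[st.v] += 1; path.push_back(st.v); }
      else path.push_back(g.add_node(b));
    } else if (st.mv == 2) { // insertion: new node
      path.push_back(g.add_node(read[st.i - 1]));
    } // deletions: node skipped, nothing on the read path
  }
  // leading read bases not covered by steps (aligned before the first node
  // via the virtual source) become a prefix of new nodes
  int covered = 0;
  for (auto &st : steps) if (st.mv != 1) covered++;
  if (covered < L) {
    std::vector<int> prefix;
    for (int j = 0; j < L - covered; ++j) prefix.push_back(g.add_node(read[j]));
    prefix.insert(prefix.end(), path.begin(), path.end());
    path = prefix;
  }
  if (path.empty()) stop("empty POA read path");
  for (size_t j = 0; j + 1 < path.size(); ++j) g.add_edge(path[j], path[j + 1]);
  g.start_count[path.front()] += 1;
  g.end_count[path.back()] += 1;
  return best_score;
}

} // namespace

// [[Rcpp::export(name = ".poa_build_cpp")]]
List poa_build_cpp(CharacterVector reads, int match, int mismatch, int gap) {
  if (reads.size() == 0) stop("no reads");
  Graph g;
  NumericVector scores(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    if (s.empty()) stop("empty read");
    scores[r] = align_and_insert(g, s, match, mismatch, gap);
  }
  scores[0] = NA_REAL; // the seed read is not aligned, it defines the graph

  int n = (int)g.n();
  int m = 0;
  for (int u = 0; u < n; ++u) m += (int)g.out[u].size();
  IntegerVector ef(m), et(m), ew(m);
  int k = 0;
  for (int u = 0; u < n; ++u)
    for (auto &e : g.out[u]) { ef[k] = u + 1; et[k] = e.first + 1; ew[k] = e.second; ++k; }

  CharacterVector bases(n);
  for (int u = 0; u < n; ++u) bases[u] = std::string(1, g.base[u]);

  // heaviest start-to-end path: weights are edge traversal counts plus the
  // virtual start/end counts; predecessor ties broken by higher node support,
  // then lexicographically smaller base
  std::vector<int> order = g.topo_order();
  std::vector<long long> best(n, LLONG_MIN / 4);
  std::vector<int> from(n, -2);
  for (int v : order) {
    if (g.start_count[v] > 0) { best[v] = g.start_count[v]; from[v] = -1; }
    for (int u : g.in[v]) {
      int w = 0;
      for (auto &e : g.out[u]) if (e.first == v) { w = e.second; break; }
      long long cand = best[u] + w;
      if (cand > best[v] ||
          (cand == best[v] && from[v] >= 0 &&
           (g.support[u] > g.support[from[v]] ||
            (g.support[u] == g.support[from[v]] && g.base[u] < g.base[from[v]])))) {
        best[v] = cand;
        from[v] = u;
      }
    }
  }
  long long bs = LLONG_MIN; int be = -1;
  for (int v = 0; v < n; ++v) {
    if (g.end_count[v] == 0) continue;
    long long sc = best[v] + g.end_count[v];
    if (sc > bs || (sc == bs && be >= 0 &&
                    (g.support[v] > g.support[be] ||
                     (g.support[v] == g.support[be] && g.base[v] < g.base[be])))) {
      bs = sc; be = v;
    }
  }
  if (be < 0) stop("POA consensus failed: no end node");
  std::string consensus;
  std::vector<int> cpath, csup;
  for (int v = be; v >= 0; v = from[v]) cpath.push_back(v);
  std::reverse(cpath.begin(), cpath.end());
  for (int v : cpath) { consensus.push_back(g.base[v]); csup.push_back(g.support[v]); }

  return List::create(
    _["bases"] = bases,
    _["support"] = IntegerVector(g.support.begin(), g.support.end()),
    _["start_count"] = IntegerVector(g.start_count.begin(), g.start_count.end()),
    _["end_count"] = IntegerVector(g.end_count.begin(), g.end_count.end()),
    _["edge_from"] = ef, _["edge_to"] = et, _["edge_weight"] = ew,
    _["scores"] = scores,
    _["consensus"] = consensus,
    _["consensus_support"] = IntegerVector(csup.begin(), csup.end()),
    _["consensus_path"] = IntegerVector(cpath.begin(), cpath.end()) + 1);
}
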