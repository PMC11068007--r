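// Exact signed graphlet census and ensemble helpers.
//
// Node ids are 0-based; edges come in as an E x 2 integer matrix with
// from < to, plus a sign vector in {+1,-1}. Pattern lookup tables map a
// bitmask (bit i set <=> canonical-order edge i is negative) to a 0-based
// pattern index; they are built in R from the catalog so the taxonomy lives
// in one place.
//
// Enumeration strategy (each occurrence visited exactly once):
//   triangle: per edge (u,v), common neighbours w > v
//   squareX : per edge (u,v) with u,v the two smallest labels, pairs of
//             common neighbours (w1 < w2, both > v) that are adjacent
//   squareZ : per edge (u,v) as the diamond diagonal, pairs of common
//             neighbours that are NOT adjacent
//   square  : per minimum node u, wedge pairing over distance-2 nodes
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, int>>> nbr;  // (neighbour, edge id), sorted
  std::unordered_set<int64_t> eset;
  int64_t key(int u, int v) const {
    if (u > v) std::swap(u, v);
    return (int64_t)u * n + v;
  }
  bool has(int u, int v) const { return eset.count(key(u, v)) > 0; }
};

Graph build_graph(int n, const IntegerMatrix& edges) {
  Graph g;
  g.n = n;
  g.nbr.assign(n, {});
  int E = edges.nrow();
  g.eset.reserve(E * 2);
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    g.nbr[u].push_back({v, e});
    g.nbr[v].push_back({u, e});
    g.eset.insert(g.key(u, v));
  }
  for (int i = 0; i < n; ++i) std::sort(g.nbr[i].begin(), g.nbr[i].end());
  return g;
}

// K4 canonical edge order on sorted nodes (a,b,c,d): pairs
// 0:ab 1:ac 2:ad 3:bc 4:bd 5:cd
const int k4_pairs[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
// dropping K4 edge d leaves a diamond whose degree-2 nodes are the endpoints
// of d; canonical diamond edge order (r-p, p-s, s-q, q-r, r-s) expressed as
// K4 edge indices, for each dropped edge:
const int k4_drop_diamond[6][5] = {
  {1,2,4,3,5},  // drop ab: p=a q=b r=c s=d
  {0,2,5,3,4},  // drop ac: p=a q=c r=b s=d
  {0,1,5,4,3},  // drop ad: p=a q=d r=b s=c
  {0,4,5,1,2},  // drop bc: p=b q=c r=a s=d
  {0,3,5,2,1},  // drop bd: p=b q=d r=a s=c
  {1,3,4,2,0},  // drop cd: p=c q=d r=a s=b
};
// dropping two disjoint K4 edges leaves a 4-cycle; cycle edge order as K4
// edge indices for the three diagonal pairings:
const int k4_drop_square[3][4] = {
  {1,3,4,2},  // drop {ab,cd}: cycle a-c-b-d
  {0,3,5,2},  // drop {ac,bd}: cycle a-b-c-d
  {0,4,5,1},  // drop {ad,bc}: cycle a-b-d-c
};

struct Counters {
  std::vector<double> graphlet, motif;
  const IntegerVector *lut_tri, *lut_x, *lut_z, *lut_s;
  bool motifs;
  void init(int npat, const IntegerVector& lt, const IntegerVector& lx,
            const IntegerVector& lz, const IntegerVector& ls, bool do_motifs) {
    graphlet.assign(npat, 0.0);
    motif.assign(npat, 0.0);
    lut_tri = &lt; lut_x = &lx; lut_z = &lz; lut_s = &ls;
    motifs = do_motifs;
  }
  inline void tri(int mask) {
    graphlet[(*lut_tri)[mask]] += 1;
    if (motifs) motif[(*lut_tri)[mask]] += 1;
  }
  inline void squareX(int mask6) {
    graphlet[(*lut_x)[mask6]] += 1;
    if (!motifs) return;
    motif[(*lut_x)[mask6]] += 1;
    for (int d = 0; d < 6; ++d) {
      int mz = 0;
      for (int b = 0; b < 5; ++b) mz |= ((mask6 >> k4_drop_diamond[d][b]) & 1) << b;
      motif[(*lut_z)[mz]] += 1;
    }
    for (int d = 0; d < 3; ++d) {
      int ms = 0;
      for (int b = 0; b < 4; ++b) ms |= ((mask6 >> k4_drop_square[d][b]) & 1) << b;
      motif[(*lut_s)[ms]] += 1;
    }
  }
  inline void squareZ(int mask5) {
    graphlet[(*lut_z)[mask5]] += 1;
    if (!motifs) return;
    motif[(*lut_z)[mask5]] += 1;
    motif[(*lut_s)[mask5 & 15]] += 1;  // drop the diagonal
  }
  inline void square(int mask4) {
    graphlet[(*lut_s)[mask4]] += 1;
    if (motifs) motif[(*lut_s)[mask4]] += 1;
  }
};

struct OccCollect {
  bool collect = false;
  std::vector<int> tri, x, z, s;  // edge-id tuples, row-major
};

// neg[e] = 1 if edge e negative
void run_census(const Graph& g, const std::vector<int>& neg, Counters& C,
                OccCollect& O, bool do_triangle = true, bool do_four = true) {
  int n = g.n;
  if (!do_triangle && !do_four) return;
  std::vector<std::pair<int, int>> common;  // (w, ...) reused
  // triangles, K4, diamonds: per edge (u,v) with u < v
  for (int u = 0; u < n; ++u) {
    for (auto& pv : g.nbr[u]) {
      int v = pv.first, e_uv = pv.second;
      if (v < u) continue;
      // common neighbours of u and v with their edge ids
      common.clear();
      std::vector<std::pair<int, std::pair<int, int>>> com;  // (w, (e_uw, e_vw))
      {
        auto it1 = g.nbr[u].begin(), end1 = g.nbr[u].end();
        auto it2 = g.nbr[v].begin(), end2 = g.nbr[v].end();
        while (it1 != end1 && it2 != end2) {
          if (it1->first < it2->first) ++it1;
          else if (it2->first < it1->first) ++it2;
          else {
            com.push_back({it1->first, {it1->second, it2->second}});
            ++it1; ++it2;
          }
        }
      }
      if (do_triangle) for (auto& cw : com) {
        int w = cw.first;
        if (w > v) {  // triangle u < v < w, edges (uv, uw, vw)
          int e_uw = cw.second.first, e_vw = cw.second.second;
          int mask = neg[e_uv] | (neg[e_uw] << 1) | (neg[e_vw] << 2);
          C.tri(mask);
          if (O.collect) { O.tri.push_back(e_uv); O.tri.push_back(e_uw); O.tri.push_back(e_vw); }
        }
      }
      // pairs of common neighbours
      if (do_four) for (size_t i = 0; i < com.size(); ++i) {
        for (size_t j = i + 1; j < com.size(); ++j) {
          int w1 = com[i].first, w2 = com[j].first;  // w1 < w2
          bool adj = g.has(w1, w2);
          if (adj) {
            if (w1 > v) {
              // K4 on sorted nodes (u, v, w1, w2); u < v < w1 < w2
              auto it = g.eset.find(g.key(w1, w2));
              (void)it;
              // need edge id of (w1,w2): binary search in nbr[w1]
              int e_ww = -1;
              {
                auto& lst = g.nbr[w1];
                auto pos = std::lower_bound(lst.begin(), lst.end(),
                                            std::make_pair(w2, -1));
                e_ww = pos->second;
              }
              int e_uw1 = com[i].second.first, e_vw1 = com[i].second.second;
              int e_uw2 = com[j].second.first, e_vw2 = com[j].second.second;
              // edge order (ab,ac,ad,bc,bd,cd) = (uv, uw1, uw2, vw1, vw2, w1w2)
              int mask = neg[e_uv] | (neg[e_uw1] << 1) | (neg[e_uw2] << 2) |
                         (neg[e_vw1] << 3) | (neg[e_vw2] << 4) | (neg[e_ww] << 5);
              C.squareX(mask);
              if (O.collect) {
                O.x.push_back(e_uv); O.x.push_back(e_uw1); O.x.push_back(e_uw2);
                O.x.push_back(e_vw1); O.x.push_back(e_vw2); O.x.push_back(e_ww);
              }
            }
          } else {
            // diamond with diagonal (u,v), degree-2 nodes w1, w2
            // roles a=u b=w1 c=v d=w2; edges (ab,bc,cd,da,ac) =
            // (u-w1, w1-v, v-w2, w2-u, u-v)
            int e_uw1 = com[i].second.first, e_vw1 = com[i].second.second;
            int e_uw2 = com[j].second.first, e_vw2 = com[j].second.second;
            int mask = neg[e_uw1] | (neg[e_vw1] << 1) | (neg[e_vw2] << 2) |
                       (neg[e_uw2] << 3) | (neg[e_uv] << 4);
            C.squareZ(mask);
            if (O.collect) {
              O.z.push_back(e_uw1); O.z.push_back(e_vw1); O.z.push_back(e_vw2);
              O.z.push_back(e_uw2); O.z.push_back(e_uv);
            }
          }
        }
      }
    }
  }
  // chordless squares: u is the minimum node of the cycle
  if (!do_four) return;
  std::vector<std::vector<std::array<int, 2>>> bucket(n);  // w -> (v, e_vw)
  std::vector<int> touched;
  std::vector<int> e_to_u(n, -1);
  for (int u = 0; u < n; ++u) {
    touched.clear();
    for (auto& pv : g.nbr[u]) e_to_u[pv.first] = pv.second;
    for (auto& pv : g.nbr[u]) {
      int v = pv.first;
      if (v <= u) continue;
      for (auto& pw : g.nbr[v]) {
        int w = pw.first;
        if (w <= u || w == u) continue;
        if (e_to_u[w] >= 0) continue;  // adjacent to u -> not chordless here
        if (bucket[w].empty()) touched.push_back(w);
        bucket[w].push_back({v, pw.second});
      }
    }
    for (int w : touched) {
      auto& L = bucket[w];
      for (size_t i = 0; i < L.size(); ++i) {
        for (size_t j = i + 1; j < L.size(); ++j) {
          int v1 = L[i][0], v2 = L[j][0];  // v1 < v2 (nbr sorted)
          if (g.has(v1, v2)) continue;     // chord -> not an induced square
          // cycle u - v1 - w - v2; edges (01,12,23,30) =
          // (u-v1, v1-w, w-v2, v2-u)
          int e1 = e_to_u[v1], e2 = L[i][1], e3 = L[j][1], e4 = e_to_u[v2];
          int mask = neg[e1] | (neg[e2] << 1) | (neg[e3] << 2) | (neg[e4] << 3);
          C.square(mask);
          if (O.collect) {
            O.s.push_back(e1); O.s.push_back(e2); O.s.push_back(e3); O.s.push_back(e4);
          }
        }
      }
      L.clear();
    }
    for (auto& pv : g.nbr[u]) e_to_u[pv.first] = -1;
  }
}

std::vector<int> neg_vec(const IntegerVector& signs) {
  std::vector<int> neg(signs.size());
  for (int i = 0; i < signs.size(); ++i) neg[i] = signs[i] < 0 ? 1 : 0;
  return neg;
}

IntegerMatrix tuple_matrix(const std::vector<int>& v, int k) {
  int rows = v.size() / k;
  IntegerMatrix m(rows, k);
  for (int r = 0; r < rows; ++r)
    for (int c = 0; c < k; ++c) m(r, c) = v[r * k + c];
  return m;
}

}  // namespace

// [[Rcpp::export]]
List cpp_census(int n, IntegerMatrix edges, IntegerVector signs,
                IntegerVector lut_tri, IntegerVector lut_x,
                IntegerVector lut_z, IntegerVector lut_s,
                bool motifs, bool do_triangle, bool do_four) {
  Graph g = build_graph(n, edges);
  std::vector<int> neg = neg_vec(signs);
  Counters C;
  C.init(35, lut_tri, lut_x, lut_z, lut_s, motifs);
  OccCollect O;
  run_census(g, neg, C, O, do_triangle, do_four);
  return List::create(_["graphlet"] = NumericVector(C.graphlet.begin(), C.graphlet.end()),
                      _["motif"] = NumericVector(C.motif.begin(), C.motif.end()));
}

// [[Rcpp::export]]
List cpp_occurrences(int n, IntegerMatrix edges, IntegerVector signs,
                     IntegerVector lut_tri, IntegerVector lut_x,
                     IntegerVector lut_z, IntegerVector lut_s) {
  Graph g = build_graph(n, edges);
  std::vector<int> neg = neg_vec(signs);
  Counters C;
  C.init(35, lut_tri, lut_x, lut_z, lut_s, false);
  OccCollect O;
  O.collect = true;
  run_census(g, neg, C, O);
  return List::create(_["triangle"] = tuple_matrix(O.tri, 3),
                      _["squareX"] = tuple_matrix(O.x, 6),
                      _["squareZ"] = tuple_matrix(O.z, 5),
                      _["square"] = tuple_matrix(O.s, 4));
}

// Re-score cached occurrences under a new sign assignment.
// [[Rcpp::export]]
List cpp_score_occurrences(List occ, IntegerVector signs,
                           IntegerVector lut_tri, IntegerVector lut_x,
                           IntegerVector lut_z, IntegerVector lut_s,
                           bool motifs) {
  std::vector<int> neg = neg_vec(signs);
  Counters C;
  C.init(35, lut_tri, lut_x, lut_z, lut_s, motifs);
  IntegerMatrix tri = occ["triangle"], x = occ["squareX"],
                z = occ["squareZ"], s = occ["square"];
  for (int r = 0; r < tri.nrow(); ++r) {
    int mask = neg[tri(r,0)] | (neg[tri(r,1)] << 1) | (neg[tri(r,2)] << 2);
    C.tri(mask);
  }
  for (int r = 0; r < x.nrow(); ++r) {
    int mask = 0;
    for (int c = 0; c < 6; ++c) mask |= neg[x(r,c)] << c;
    C.squareX(mask);
  }
  for (int r = 0; r < z.nrow(); ++r) {
    int mask = 0;
    for (int c = 0; c < 5; ++c) mask |= neg[z(r,c)] << c;
    C.squareZ(mask);
  }
  for (int r = 0; r < s.nrow(); ++r) {
    int mask = 0;
    for (int c = 0; c < 4; ++c) mask |= neg[s(r,c)] << c;
    C.square(mask);
  }
  return List::create(_["graphlet"] = NumericVector(C.graphlet.begin(), C.graphlet.end()),
                      _["motif"] = NumericVector(C.motif.begin(), C.motif.end()));
}

// Degree-preserving double edge swaps. Signs ride on edge indices; in signed
// mode the two candidate edges are drawn from the same sign class so signed
// degrees are conserved. Aborted attempts (coinciding endpoints or an edge
// that already exists with either sign) count toward the attempt budget.
// [[Rcpp::export]]
List cpp_rewire(int n, IntegerMatrix edges, IntegerVector signs,
                double attempts, bool signed_mode) {
  int E = edges.nrow();
  std::vector<int> eu(E), ev(E);
  std::unordered_set<int64_t> eset;
  eset.reserve(E * 2);
  auto key = [&](int a, int b) {
    if (a > b) std::swap(a, b);
    return (int64_t)a * n + b;
  };
  for (int e = 0; e < E; ++e) {
    eu[e] = edges(e, 0); ev[e] = edges(e, 1);
    eset.insert(key(eu[e], ev[e]));
  }
  std::vector<std::vector<int>> by_sign(2);
  if (signed_mode) {
    for (int e = 0; e < E; ++e) by_sign[signs[e] > 0 ? 0 : 1].push_back(e);
  }
  RNGScope scope;
  double performed = 0;
  for (double a = 0; a < attempts; ++a) {
    int e1, e2;
    if (signed_mode) {
      e1 = (int)(unif_rand() * E);
      if (e1 >= E) e1 = E - 1;
      auto& cls = by_sign[signs[e1] > 0 ? 0 : 1];
      if (cls.size() < 2) continue;
      e2 = cls[(int)(unif_rand() * cls.size()) % cls.size()];
    } else {
      e1 = (int)(unif_rand() * E) % E;
      e2 = (int)(unif_rand() * E) % E;
    }
    if (e1 == e2) continue;
    int A = eu[e1], B = ev[e1], C = eu[e2], D = ev[e2];
    if (A == C || A == D || B == C || B == D) continue;
    int nu1, nv1, nu2, nv2;
    if (unif_rand() < 0.5) {  // A-D, C-B
      nu1 = A; nv1 = D; nu2 = C; nv2 = B;
    } else {                  // A-C, B-D
      nu1 = A; nv1 = C; nu2 = B; nv2 = D;
    }
    if (eset.count(key(nu1, nv1)) || eset.count(key(nu2, nv2))) continue;
    eset.erase(key(A, B));
    eset.erase(key(C, D));
    eset.insert(key(nu1, nv1));
    eset.insert(key(nu2, nv2));
    eu[e1] = std::min(nu1, nv1); ev[e1] = std::max(nu1, nv1);
    eu[e2] = std::min(nu2, nv2); ev[e2] = std::max(nu2, nv2);
    performed += 1;
  }
  IntegerMatrix out(E, 2);
  for (int e = 0; e < E; ++e) { out(e, 0) = eu[e]; out(e, 1) = ev[e]; }
  return List::create(_["edges"] = out, _["performed"] = performed);
}

// Edge-copying growth: start from a +++ triangle; each new node t attaches
// to a uniformly chosen existing node v with a positive sign w.p. q, and
// independently copies each edge (v,u) w.p. p_copy, keeping the copied sign
// when the attachment is positive and reversing it when negative.
// [[Rcpp::export]]
List cpp_ec_generate(int n, double q, double p_copy) {
  std::vector<int> eu, ev, es;
  std::vector<std::vector<std::pair<int, int>>> adj(n);  // (neighbour, sign)
  auto add_edge = [&](int a, int b, int s) {
    eu.push_back(std::min(a, b));
    ev.push_back(std::max(a, b));
    es.push_back(s);
    adj[a].push_back({b, s});
    adj[b].push_back({a, s});
  };
  RNGScope scope;
  add_edge(0, 1, 1); add_edge(0, 2, 1); add_edge(1, 2, 1);
  for (int t = 3; t < n; ++t) {
    int v = (int)(unif_rand() * t) % t;
    int s_att = unif_rand() < q ? 1 : -1;
    size_t deg = adj[v].size();
    for (size_t i = 0; i < deg; ++i) {  // neighbours of v before t joins
      if (unif_rand() < p_copy) {
        int u = adj[v][i].first, sig = adj[v][i].second;
        add_edge(t, u, s_att > 0 ? sig : -sig);
      }
    }
    add_edge(t, v, s_att);
  }
  int E = eu.size();
  IntegerMatrix out(E, 2);
  IntegerVector sg(E);
  for (int e = 0; e < E; ++e) { out(e, 0) = eu[e]; out(e, 1) = ev[e]; sg[e] = es[e]; }
  return List::create(_["edges"] = out, _["signs"] = sg);
}
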