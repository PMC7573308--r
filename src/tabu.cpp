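#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Data are passed collapsed: `configs` holds the distinct discrete
// configurations (1-based integer codes, one column per variable) and
// `weights` their multiplicities, so every family score is O(#distinct rows)
// instead of O(n).  Bootstrap resamples only change `weights`.

static const double CELL_CAP = 5e7; // refuse absurd parent-state spaces

// BIC (natural log, penalty (ln N)/2 per free parameter) of one node given a
// parent set.  Returns -Inf when the parent-state space exceeds CELL_CAP.
static double family_bic(const IntegerMatrix& configs,
                         const NumericVector& weights,
                         int node,
                         const std::vector<int>& parents,
                         const IntegerVector& nlev,
                         double n_total) {
  const int r = nlev[node];
  double qd = 1.0;
  for (int p : parents) qd *= nlev[p];
  if (qd * r > CELL_CAP) return R_NegInf;
  const int q = (int) qd;
  std::vector<double> counts((size_t) q * r, 0.0);
  const int m = configs.nrow();
  for (int u = 0; u < m; ++u) {
    int j = 0, stride = 1;
    for (int p : parents) {
      j += (configs(u, p) - 1) * stride;
      stride *= nlev[p];
    }
    counts[(size_t) j * r + (configs(u, node) - 1)] += weights[u];
  }
  double loglik = 0.0;
  for (int j = 0; j < q; ++j) {
    double nj = 0.0;
    for (int k = 0; k < r; ++k) nj += counts[(size_t) j * r + k];
    if (nj <= 0.0) continue;
    for (int k = 0; k < r; ++k) {
      double njk = counts[(size_t) j * r + k];
      if (njk > 0.0) loglik += njk * std::log(njk / nj);
    }
  }
  return loglik - 0.5 * std::log(n_total) * qd * (r - 1);
}

// [[Rcpp::export(name = ".family_bic_cpp")]]
double family_bic_cpp(IntegerMatrix configs, NumericVector weights,
                      int node, IntegerVector parents, IntegerVector nlev) {
  double n_total = 0.0;
  for (double w : weights) n_total += w;
  std::vector<int> ps(parents.begin(), parents.end());
  return family_bic(configs, weights, node, ps, nlev, n_total);
}

// ---- Tabu search ----------------------------------------------------------

struct Searcher {
  const IntegerMatrix& configs;
  const NumericVector& weights;
  const IntegerVector& nlev;
  int p;
  double n_total;
  std::vector<char> adj;             // p*p, adj[u*p+v] = arc u->v
  std::unordered_map<std::uint64_t, double> cache;

  Searcher(const IntegerMatrix& c, const NumericVector& w,
           const IntegerVector& nl)
    : configs(c), weights(w), nlev(nl), p(nl.size()), adj((size_t) p * p, 0) {
    n_total = 0.0;
    for (double x : w) n_total += x;
  }

  std::uint64_t parent_mask(int v) const {
    std::uint64_t m = 0;
    for (int u = 0; u < p; ++u) if (adj[(size_t) u * p + v]) m |= (1ULL << u);
    return m;
  }

  double score_mask(int v, std::uint64_t mask) {
    std::uint64_t key = ((std::uint64_t) v << 56) ^ mask;
    auto it = cache.find(key);
    if (it != cache.end()) return it->second;
    std::vector<int> ps;
    for (int u = 0; u < p; ++u) if (mask & (1ULL << u)) ps.push_back(u);
    double s = family_bic(configs, weights, v, ps, nlev, n_total);
    cache.emplace(key, s);
    return s;
  }

  // is there a directed path from s to t (ignoring arc `skip_u`->`skip_v`)?
  bool has_path(int s, int t, int skip_u, int skip_v) const {
    if (s == t) return true;
    std::vector<char> seen((size_t) p, 0);
    std::vector<int> stack{s};
    seen[s] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v = 0; v < p; ++v) {
        if (!adj[(size_t) u * p + v]) continue;
        if (u == skip_u && v == skip_v) continue;
        if (v == t) return true;
        if (!seen[v]) { seen[v] = 1; stack.push_back(v); }
      }
    }
    return false;
  }
};

// Move encoding: type 0 = add u->v, 1 = delete u->v, 2 = reverse u->v.
// [[Rcpp::export(name = ".tabu_search_cpp")]]
List tabu_search_cpp(IntegerMatrix configs, NumericVector weights,
                     IntegerVector nlev, LogicalMatrix blacklist,
                     LogicalMatrix whitelist, LogicalMatrix start,
                     int tenure, int max_iter, int max_no_improve) {
  const int p = nlev.size();
  if (p > 56) stop("tabu search supports at most 56 nodes");
  Searcher S(configs, weights, nlev);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v)
      if (start(u, v)) S.adj[(size_t) u * p + v] = 1;

  std::vector<double> fs(p);
  double current = 0.0;
  for (int v = 0; v < p; ++v) {
    fs[v] = S.score_mask(v, S.parent_mask(v));
    current += fs[v];
  }
  double best = current;
  std::vector<char> best_adj = S.adj;

  std::vector<int> tabu_until((size_t) p * p, -1);
  int no_improve = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    double best_delta = R_NegInf;
    int bu = -1, bv = -1, btype = -1;
    double b_new_v = 0.0, b_new_u = 0.0;

    for (int u = 0; u < p; ++u) {
      for (int v = 0; v < p; ++v) {
        if (u == v) continue;
        bool present = S.adj[(size_t) u * p + v];
        bool tabu = tabu_until[(size_t) u * p + v] > iter ||
                    tabu_until[(size_t) v * p + u] > iter;
        for (int type = 0; type < 3; ++type) {
          if (type == 0 && present) continue;
          if (type != 0 && !present) continue;
          if (type == 0 && (blacklist(u, v) || S.has_path(v, u, -1, -1)))
            continue;
          if (type != 0 && whitelist(u, v)) continue;
          if (type == 2 && (blacklist(v, u) || S.has_path(u, v, u, v)))
            continue;
          double new_v, new_u = 0.0, delta;
          std::uint64_t mv = S.parent_mask(v);
          if (type == 0) {
            new_v = S.score_mask(v, mv | (1ULL << u));
            delta = new_v - fs[v];
          } else if (type == 1) {
            new_v = S.score_mask(v, mv & ~(1ULL << u));
            delta = new_v - fs[v];
          } else {
            new_v = S.score_mask(v, mv & ~(1ULL << u));
            new_u = S.score_mask(u, S.parent_mask(u) | (1ULL << v));
            delta = (new_v - fs[v]) + (new_u - fs[u]);
          }
          if (!R_finite(delta)) continue;
          // aspiration: a tabu move is admissible if it beats the incumbent
          if (tabu && current + delta <= best) continue;
          // strict margin so score-equivalent moves resolve to the first
          // candidate in lexicographic order, independent of rounding noise
          if (delta > best_delta + 1e-9) {
            best_delta = delta; bu = u; bv = v; btype = type;
            b_new_v = new_v; b_new_u = new_u;
          }
        }
      }
    }

    if (btype < 0) break; // no admissible neighbour
    if (btype == 0) {
      S.adj[(size_t) bu * p + bv] = 1;
    } else if (btype == 1) {
      S.adj[(size_t) bu * p + bv] = 0;
    } else {
      S.adj[(size_t) bu * p + bv] = 0;
      S.adj[(size_t) bv * p + bu] = 1;
      fs[bu] = b_new_u;
    }
    fs[bv] = b_new_v;
    current += best_delta;
    tabu_until[(size_t) bu * p + bv] = iter + 1 + tenure;

    if (current > best + 1e-12) {
      best = current;
      best_adj = S.adj;
      no_improve = 0;
    } else if (++no_improve >= max_no_improve) {
      break;
    }
  }

  LogicalMatrix out(p, p);
  for (int u = 0; u < p; ++u)
    for (int v = 0; v < p; ++v)
      out(u, v) = best_adj[(size_t) u * p + v] != 0;
  return List::create(_["adjacency"] = out, _["score"] = best);
}
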