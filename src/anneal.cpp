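// Metropolis-Hastings simulated annealing over vertex label assignments,
// minimizing the compression entropy log Z.  The type table (sorted label
// multiset of each edge -> count) is updated incrementally per proposal and
// rolled back exactly on rejection; log Z is re-summed over the realized
// lambda-types, whose number is small and independent of |E|.
//
// Model codes: 0 = simple, 1 = multiset, 2 = degree-corrected.
// All entropies in nats.  Uses R's RNG so set.seed() governs determinism.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

typedef std::map<std::vector<int>, double> TypeMap;

// log C(N, k) with N possibly huge/non-integer, given as logN.  Small-k
// product form avoids lgamma cancellation; logN > 500 would overflow exp().
static double simple_term(double logN, double k) {
  if (k <= 0) return 0.0;
  if (logN > 500.0) return k * logN - lgamma(k + 1.0);
  double N = std::exp(logN);
  if (k > N + 1e-9) return R_PosInf; // infeasible: no compatible hypergraph
  if (k < 64.0) {
    double s = 0.0;
    for (int j = 0; j < (int)k; j++) s += std::log(N - j);
    return s - lgamma(k + 1.0);
  }
  return lgamma(N + 1.0) - lgamma(k + 1.0) - lgamma(N - k + 1.0);
}

struct State {
  int n, m, model;
  std::vector< std::vector<int> > edges;       // sorted vertex ids, 0-based
  std::vector< std::vector<int> > edge_labels; // sorted label multiset per edge
  std::vector< std::vector<int> > inc;         // vertex -> incident edge ids (unique)
  std::vector<int> labels;                     // 0-based cluster labels
  std::vector<double> sizes;                   // cluster sizes
  std::vector<double> esum;                    // per-cluster degree sums e_i
  std::vector<double> deg;                     // vertex degrees (with multiplicity)
  TypeMap types;                               // lambda-type -> e_lambda

  double log_z() const {
    double lz = 0.0;
    if (model == 2)
      for (int i = 0; i < m; i++) lz += lgamma(esum[i] + 1.0);
    for (TypeMap::const_iterator it = types.begin(); it != types.end(); ++it) {
      double cnt = it->second;
      if (cnt <= 0.5) continue;
      const std::vector<int>& lab = it->first;
      if (model == 2) {
        double lam_fac = 0.0;
        size_t p = 0;
        while (p < lab.size()) {
          size_t q = p;
          while (q < lab.size() && lab[q] == lab[p]) q++;
          lam_fac += lgamma((double)(q - p) + 1.0);
          p = q;
        }
        lz += -lgamma(cnt + 1.0) - cnt * lam_fac;
      } else {
        double logN = 0.0;
        bool feasible = true;
        size_t p = 0;
        while (p < lab.size()) {
          size_t q = p;
          while (q < lab.size() && lab[q] == lab[p]) q++;
          double li = (double)(q - p), sz = sizes[lab[p]];
          if (li > sz) { feasible = false; break; }
          logN += Rf_lchoose(sz, li);
          p = q;
        }
        if (!feasible) return R_PosInf;
        if (model == 0) {
          double t = simple_term(logN, cnt);
          if (t == R_PosInf) return R_PosInf;
          lz += t;
        } else {
          lz += cnt * logN;
        }
      }
    }
    return lz;
  }

  // relabel vertex v (multiplicity-aware) from a to b in all incident edges
  void move(int v, int a, int b) {
    const std::vector<int>& ie = inc[v];
    for (size_t k = 0; k < ie.size(); k++) {
      std::vector<int>& el = edge_labels[ie[k]];
      const std::vector<int>& ev = edges[ie[k]];
      TypeMap::iterator it = types.find(el);
      it->second -= 1.0;
      if (it->second <= 0.5) types.erase(it);
      int mult = 0;
      for (size_t j = 0; j < ev.size(); j++) if (ev[j] == v) mult++;
      int done = 0;
      for (size_t j = 0; j < el.size() && done < mult; j++)
        if (el[j] == a) { el[j] = b; done++; }
      std::sort(el.begin(), el.end());
      types[el] += 1.0;
    }
    sizes[a] -= 1.0; sizes[b] += 1.0;
    if (model == 2) { esum[a] -= deg[v]; esum[b] += deg[v]; }
  }
};

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(List edges, int n, int m, int model, int steps,
                double beta_rate, IntegerVector init, bool record_trace) {
  State s;
  s.n = n; s.m = m; s.model = model;
  int nedge = edges.size();
  s.edges.resize(nedge);
  s.edge_labels.resize(nedge);
  s.inc.resize(n);
  s.deg.assign(n, 0.0);
  s.labels.assign(init.begin(), init.end()); // 0-based from R wrapper
  s.sizes.assign(m, 0.0);
  s.esum.assign(m, 0.0);
  for (int v = 0; v < n; v++) s.sizes[s.labels[v]] += 1.0;
  for (int e = 0; e < nedge; e++) {
    IntegerVector ev = edges[e];
    std::vector<int> vs(ev.begin(), ev.end()); // 0-based, sorted by caller
    s.edges[e] = vs;
    std::vector<int> el(vs.size());
    int prev = -1;
    for (size_t j = 0; j < vs.size(); j++) {
      el[j] = s.labels[vs[j]];
      s.deg[vs[j]] += 1.0;
      if (vs[j] != prev) { s.inc[vs[j]].push_back(e); prev = vs[j]; }
    }
    std::sort(el.begin(), el.end());
    s.edge_labels[e] = el;
    s.types[el] += 1.0;
  }
  for (int v = 0; v < n; v++) s.esum[s.labels[v]] += s.deg[v];

  double cur = s.log_z();
  std::vector<int> best(s.labels);
  double best_lz = cur;
  long accepted = 0;
  NumericVector trace_cur(record_trace ? steps : 0),
                trace_best(record_trace ? steps : 0);

  for (int t = 0; t < steps; t++) {
    double beta = (t + 1) * beta_rate;
    int v = (int)(unif_rand() * n); if (v >= n) v = n - 1;
    int b = (int)(unif_rand() * m); if (b >= m) b = m - 1;
    int a = s.labels[v];
    if (b == a) {
      accepted++; // delta = 0, always accepted; state unchanged
    } else {
      s.move(v, a, b);
      double prop = s.log_z();
      bool accept;
      if (prop == R_PosInf) {
        accept = (cur == R_PosInf);
      } else if (cur == R_PosInf || prop <= cur) {
        accept = true;
      } else {
        accept = unif_rand() < std::exp(-beta * (prop - cur));
      }
      if (accept) {
        s.labels[v] = b;
        cur = prop;
        accepted++;
        if (cur < best_lz) { best_lz = cur; best = s.labels; }
      } else {
        s.move(v, b, a); // exact rollback
      }
    }
    if (record_trace) { trace_cur[t] = cur; trace_best[t] = best_lz; }
  }

  List out = List::create(
    _["best"] = IntegerVector(best.begin(), best.end()),
    _["final"] = IntegerVector(s.labels.begin(), s.labels.end()),
    _["best_log_z"] = best_lz,
    _["final_log_z"] = cur,
    _["accepted"] = (double)accepted);
  if (record_trace) {
    out["trace_current"] = trace_cur;
    out["trace_best"] = trace_best;
  }
  return out;
}
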