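#include <Rcpp.h>
using namespace Rcpp;

// Double-edge-swap (Maslov-Sneppen) rewiring of a simple undirected graph.
// edges: m x 2 integer matrix of 0-based endpoints. attempts: proposed swaps.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".rewire_ms_cpp")]]
List rewire_ms_cpp(IntegerMatrix edges, int n, double attempts) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::vector<unsigned char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    ea[e] = a; eb[e] = b;
    adj[(size_t)a * n + b] = 1;
    adj[(size_t)b * n + a] = 1;
  }
  double accepted = 0;
  if (m >= 2) {
    for (double t = 0; t < attempts; ++t) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      // randomize which end of e2 pairs with a
      if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
      // proposed new edges: (a, d) and (c, b)
      if (a == d || c == b) continue;              // self-loop
      if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue; // multi-edge
      // remove old, insert new
      adj[(size_t)a * n + b] = 0; adj[(size_t)b * n + a] = 0;
      adj[(size_t)c * n + d] = 0; adj[(size_t)d * n + c] = 0;
      adj[(size_t)a * n + d] = 1; adj[(size_t)d * n + a] = 1;
      adj[(size_t)c * n + b] = 1; adj[(size_t)b * n + c] = 1;
      eb[e1] = d;
      ea[e2] = c; eb[e2] = b;
      accepted += 1;
    }
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) { out(e, 0) = ea[e]; out(e, 1) = eb[e]; }
  return List::create(_["edges"] = out, _["accepted"] = accepted);
}

// Simulated-annealing placement of a fixed weight multiset on a fixed
// topology so node strengths approach a target sequence.
// Energy E = sum_i (s_i - target_i)^2. Proposals swap the weights of two
// randomly chosen edges; geometric cooling per sweep (sweep = m proposals).
// [[Rcpp::export(name = ".anneal_strength_cpp")]]
List anneal_strength_cpp(IntegerMatrix edges, NumericVector weights,
                         NumericVector target, double t0frac, double cooling,
                         int maxSweeps, int stagnation) {
  int m = edges.nrow(), n = target.size();
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<double> s(n, 0.0);
  for (int e = 0; e < m; ++e) {
    s[edges(e, 0)] += w[e];
    s[edges(e, 1)] += w[e];
  }
  double E = 0;
  for (int i = 0; i < n; ++i) { double d = s[i] - target[i]; E += d * d; }
  std::vector<double> bestW = w;
  double bestE = E;
  std::vector<double> trace;
  trace.reserve(maxSweeps);

  double wmin = *std::min_element(w.begin(), w.end());
  double wmax = *std::max_element(w.begin(), w.end());
  bool degenerate = (m < 2) || (wmax - wmin) <= 1e-15 * std::max(1.0, std::abs(wmax));

  double T = t0frac * (E > 0 ? E : 1.0);
  int sinceImprove = 0;
  if (!degenerate && E > 0) {
    for (int sweep = 0; sweep < maxSweeps; ++sweep) {
      for (int it = 0; it < m; ++it) {
        int p = (int)(unif_rand() * m);
        int q = (int)(unif_rand() * m);
        if (p == q || w[p] == w[q]) continue;
        double dw = w[q] - w[p];
        int nodes[4] = { edges(p, 0), edges(p, 1), edges(q, 0), edges(q, 1) };
        double delta[4] = { dw, dw, -dw, -dw };
        // merge duplicate nodes (shared endpoints)
        int uNodes[4]; double uDelta[4]; int nu = 0;
        for (int k = 0; k < 4; ++k) {
          int found = -1;
          for (int u = 0; u < nu; ++u) if (uNodes[u] == nodes[k]) { found = u; break; }
          if (found >= 0) uDelta[found] += delta[k];
          else { uNodes[nu] = nodes[k]; uDelta[nu] = delta[k]; ++nu; }
        }
        double dE = 0;
        for (int u = 0; u < nu; ++u) {
          double s0 = s[uNodes[u]], tg = target[uNodes[u]];
          double s1 = s0 + uDelta[u];
          dE += (s1 - tg) * (s1 - tg) - (s0 - tg) * (s0 - tg);
        }
        bool accept = dE < 0;
        if (!accept && T > 0) accept = unif_rand() < std::exp(-dE / T);
        if (accept) {
          double tmp = w[p]; w[p] = w[q]; w[q] = tmp;
          for (int u = 0; u < nu; ++u) s[uNodes[u]] += uDelta[u];
          E += dE;
        }
      }
      if (E < bestE * (1 - 1e-12) && E < bestE) {
        bestE = E; bestW = w; sinceImprove = 0;
      } else {
        ++sinceImprove;
      }
      trace.push_back(bestE);
      T *= cooling;
      if (sinceImprove >= stagnation || bestE <= 1e-24) break;
    }
  }
  return List::create(_["weights"] = NumericVector(bestW.begin(), bestW.end()),
                      _["energy"] = bestE,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["sweeps"] = (int)trace.size());
}
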