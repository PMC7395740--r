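#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving edge rewiring for one edge class.
//
// Attempts n_attempts swaps. Each attempt draws two distinct eligible
// edges (a->b, c->d) and proposes (a->d, c->b). The attempt is discarded
// (not retried) when the proposal would duplicate an existing edge,
// reproduce the drawn pair unchanged, or -- in locked mode -- create a
// self-loop. In locked mode existing self-loops are excluded from the
// eligible pool, so the self-loop set is invariant. Uses R's RNG, so
// set.seed() on the R side makes the result reproducible.
//
// src/tgt are 1-based node indices. Returns the new target vector
// (sources never change, so in/out degrees are preserved).
// [[Rcpp::export]]
IntegerVector rewire_class_cpp(IntegerVector src, IntegerVector tgt,
                               int n_attempts, bool locked) {
  int m = src.size();
  std::vector<int> s(src.begin(), src.end());
  std::vector<int> t(tgt.begin(), tgt.end());
  std::vector<int> pool;
  pool.reserve(m);
  for (int i = 0; i < m; ++i) {
    if (!(locked && s[i] == t[i])) pool.push_back(i);
  }
  const long long M = 4294967311LL;  // > any node index
  std::unordered_set<long long> keys;
  keys.reserve(m * 2);
  for (int i = 0; i < m; ++i) keys.insert((long long)s[i] * M + t[i]);
  int np = (int)pool.size();
  if (np >= 2) {
    for (int att = 0; att < n_attempts; ++att) {
      int pi = (int)(unif_rand() * np);
      if (pi >= np) pi = np - 1;
      int pj = (int)(unif_rand() * (np - 1));
      if (pj >= np - 1) pj = np - 2;
      if (pj >= pi) ++pj;  // distinct second draw
      int i = pool[pi], j = pool[pj];
      int a = s[i], b = t[i], c = s[j], d = t[j];
      if (b == d || a == c) continue;           // no-op swap
      if (locked && (a == d || c == b)) continue;  // would create self-loop
      long long k1 = (long long)a * M + d;
      long long k2 = (long long)c * M + b;
      if (keys.count(k1) || keys.count(k2)) continue;  // duplicate edge
      keys.erase((long long)a * M + b);
      keys.erase((long long)c * M + d);
      keys.insert(k1);
      keys.insert(k2);
      t[i] = d;
      t[j] = b;
    }
  }
  return IntegerVector(t.begin(), t.end());
}
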