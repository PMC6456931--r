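#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// All exact k-mer hits (i, j) between two sequences, 0-based start
// positions; windows containing non-ACGT characters never match.
// [[Rcpp::export]]
IntegerMatrix enumerate_hits_cpp(std::string a, std::string b, int k) {
  auto code = [](char ch) -> int {
    switch (ch) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return -1;
    }
  };
  const int na = (int)a.size(), nb = (int)b.size();
  std::vector<std::pair<int, int>> hits;
  if (k >= 1 && k <= 31 && na >= k && nb >= k) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::unordered_multimap<uint64_t, int> index;
    index.reserve(na);
    uint64_t w = 0; int valid = 0;
    for (int i = 0; i < na; ++i) {
      int c = code(a[i]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++valid >= k) index.emplace(w, i - k + 1);
    }
    w = 0; valid = 0;
    for (int j = 0; j < nb; ++j) {
      int c = code(b[j]);
      if (c < 0) { valid = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        auto range = index.equal_range(w);
        for (auto it = range.first; it != range.second; ++it)
          hits.emplace_back(it->second, j - k + 1);
      }
    }
  }
  std::sort(hits.begin(), hits.end());
  IntegerMatrix out(hits.size(), 2);
  for (size_t t = 0; t < hits.size(); ++t) {
    out(t, 0) = hits[t].first;
    out(t, 1) = hits[t].second;
  }
  return out;
}

static int uf_find(std::vector<int>& par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

// Single-linkage clustering of hits under the group criteria:
// D = max(|i2-i1|, |j2-j1|) <= rho and |d2 - d1| <= delta, closed
// transitively. Sorting by i restricts edge probing to the rho-window
// without changing the connected components (any edge has |i2-i1| <= rho).
// Labels are renumbered by first appearance in (i, j) order.
// [[Rcpp::export]]
IntegerVector group_hits_cpp(IntegerVector i, IntegerVector j,
                             int rho, int delta) {
  const int n = i.size();
  std::vector<int> ord(n);
  for (int t = 0; t < n; ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (i[a] != i[b]) return i[a] < i[b];
    return j[a] < j[b];
  });
  std::vector<int> par(n);
  for (int t = 0; t < n; ++t) par[t] = t;
  for (int t = 0; t < n; ++t) {
    int ht = ord[t];
    for (int u = t + 1; u < n; ++u) {
      int hu = ord[u];
      if (i[hu] - i[ht] > rho) break;
      if (std::abs(j[hu] - j[ht]) > rho) continue;
      int dd = (j[hu] - i[hu]) - (j[ht] - i[ht]);
      if (std::abs(dd) > delta) continue;
      int ra = uf_find(par, ht), rb = uf_find(par, hu);
      if (ra != rb) par[ra] = rb;
    }
  }
  IntegerVector lab(n);
  std::unordered_map<int, int> remap;
  int next = 1;
  for (int t = 0; t < n; ++t) {
    int root = uf_find(par, ord[t]);
    auto it = remap.find(root);
    if (it == remap.end()) { remap[root] = next; lab[ord[t]] = next; ++next; }
    else lab[ord[t]] = it->second;
  }
  return lab;
}

// Maximum matched-bases chain under strict precedence in both reads:
// group s may precede t iff a_end[s] <= a_start[t] and b_end[s] <= b_start[t].
// No gap penalty. Deterministic tie-breaks: groups are processed in
// (a_start, b_start, a_end, b_end) order; among equal-score predecessors the
// earliest in that order wins, and the final chain ends at the earliest
// best-scoring group. Returns 1-based indices into the input, chain order.
// [[Rcpp::export]]
IntegerVector chain_groups_cpp(IntegerVector a_start, IntegerVector a_end,
                               IntegerVector b_start, IntegerVector b_end,
                               NumericVector score) {
  const int n = a_start.size();
  std::vector<int> ord(n);
  for (int t = 0; t < n; ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (a_start[x] != a_start[y]) return a_start[x] < a_start[y];
    if (b_start[x] != b_start[y]) return b_start[x] < b_start[y];
    if (a_end[x] != a_end[y]) return a_end[x] < a_end[y];
    return b_end[x] < b_end[y];
  });
  std::vector<double> f(n);
  std::vector<int> pred(n, -1);
  int best = 0;
  for (int t = 0; t < n; ++t) {
    int gt = ord[t];
    double bestf = 0.0; int bestp = -1;
    for (int s = 0; s < t; ++s) {
      int gs = ord[s];
      if (a_end[gs] <= a_start[gt] && b_end[gs] <= b_start[gt] &&
          f[s] > bestf) {
        bestf = f[s]; bestp = s;
      }
    }
    f[t] = bestf + score[gt];
    pred[t] = bestp;
    if (f[t] > f[best]) best = t;
  }
  std::vector<int> chain;
  for (int t = best; t >= 0; t = pred[t]) chain.push_back(ord[t] + 1);
  std::reverse(chain.begin(), chain.end());
  return IntegerVector(chain.begin(), chain.end());
}

// Best contiguous sub-chain whose member diagonals all lie within
// half-width w = delta + ceil(q * span) of the sub-chain's median diagonal,
// where span is the sub-chain's extent on read 1. Maximizes retained
// matched bases; single-group windows are always valid so the result is
// never empty. Returns 1-based (start, end) into the chain order.
// [[Rcpp::export]]
IntegerVector trim_collinear_cpp(NumericVector diag, IntegerVector a_start,
                                 IntegerVector a_end, NumericVector score,
                                 double delta, double q) {
  const int n = diag.size();
  double best_score = -1.0;
  int best_s = 0, best_t = 0;
  std::vector<double> sorted_d;
  for (int s = 0; s < n; ++s) {
    sorted_d.clear();
    double acc = 0.0;
    for (int t = s; t < n; ++t) {
      sorted_d.insert(std::upper_bound(sorted_d.begin(), sorted_d.end(),
                                       diag[t]), diag[t]);
      acc += score[t];
      int m = t - s + 1;
      double med = (m % 2 == 1) ? sorted_d[m / 2]
                                : 0.5 * (sorted_d[m / 2 - 1] + sorted_d[m / 2]);
      double span = (double)a_end[t] - (double)a_start[s];
      double w = delta + std::ceil(q * span);
      if (std::max(med - sorted_d.front(), sorted_d.back() - med) <= w &&
          acc > best_score) {
        best_score = acc; best_s = s; best_t = t;
      }
    }
  }
  return IntegerVector::create(best_s + 1, best_t + 1);
}

// Monte-Carlo samples of the number of Bernoulli(p) trials needed to
// complete the first run of k successes; uses R's RNG for reproducibility.
// [[Rcpp::export]]
IntegerVector sample_run_waits_cpp(double p, int k, int n) {
  IntegerVector out(n);
  for (int s = 0; s < n; ++s) {
    int run = 0, t = 0;
    for (;;) {
      ++t;
      if (R::unif_rand() < p) {
        if (++run == k) break;
      } else {
        run = 0;
      }
    }
    out[s] = t;
  }
  return out;
}
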