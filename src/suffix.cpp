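#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Suffix array by prefix doubling over an integer alphabet. O(n log^2 n),
// which is ample for the few-megabase texts an all-vs-all read index sees.
static std::vector<int> build_sa(const std::vector<int>& s) {
  const int n = (int)s.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = s[i]; }
  for (int len = 1;; len <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      int ra = a + len < n ? rnk[a + len] : -1;
      int rb = b + len < n ? rnk[b + len] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk.swap(tmp);
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's LCP construction: lcp[r] = LCP(suffix at rank r-1, rank r), lcp[0] = 0.
static std::vector<int> build_lcp(const std::vector<int>& s,
                                  const std::vector<int>& sa) {
  const int n = (int)s.size();
  std::vector<int> rank_of(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_of[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_of[i] > 0) {
      int j = sa[rank_of[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_of[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

// Encode concatenated oriented reads. A,C,G,T -> 2..5; every terminator and
// every ambiguous base gets a unique code so it never extends a common
// prefix (k-mers containing N cannot match anything, including other Ns).
// [[Rcpp::export]]
List build_suffix_index_cpp(CharacterVector seqs, bool include_rc) {
  const int nr = seqs.size();
  std::vector<int> text;
  std::vector<int> read_of, orient_of, pos_of;
  size_t total = 0;
  for (int r = 0; r < nr; ++r) total += LENGTH(STRING_ELT(seqs, r)) + 1;
  if (include_rc) total *= 2;
  text.reserve(total); read_of.reserve(total);
  orient_of.reserve(total); pos_of.reserve(total);
  int unique_code = 6;
  auto append = [&](const char* str, int len, int read, int orient, bool rc) {
    for (int t = 0; t < len; ++t) {
      char ch = rc ? str[len - 1 - t] : str[t];
      int code;
      if (rc) {
        switch (ch) {
          case 'A': code = 5; break;  // complement T
          case 'C': code = 4; break;  // complement G
          case 'G': code = 3; break;  // complement C
          case 'T': code = 2; break;  // complement A
          default:  code = unique_code++; break;
        }
      } else {
        switch (ch) {
          case 'A': code = 2; break;
          case 'C': code = 3; break;
          case 'G': code = 4; break;
          case 'T': code = 5; break;
          default:  code = unique_code++; break;
        }
      }
      text.push_back(code);
      read_of.push_back(read); orient_of.push_back(orient); pos_of.push_back(t);
    }
    text.push_back(unique_code++);           // per-sequence terminator
    read_of.push_back(-1); orient_of.push_back(-1); pos_of.push_back(-1);
  };
  for (int r = 0; r < nr; ++r) {
    const char* str = CHAR(STRING_ELT(seqs, r));
    append(str, LENGTH(STRING_ELT(seqs, r)), r, 0, false);
  }
  if (include_rc) {
    for (int r = 0; r < nr; ++r) {
      const char* str = CHAR(STRING_ELT(seqs, r));
      append(str, LENGTH(STRING_ELT(seqs, r)), r, 1, true);
    }
  }
  std::vector<int> sa = build_sa(text);
  std::vector<int> lcp = build_lcp(text, sa);
  const int n = (int)text.size();
  IntegerVector sa_out(n), lcp_out(n), read_out(n), orient_out(n), pos_out(n);
  for (int i = 0; i < n; ++i) {
    sa_out[i] = sa[i];
    lcp_out[i] = lcp[i];
    read_out[i] = read_of[sa[i]];
    orient_out[i] = orient_of[sa[i]];
    pos_out[i] = pos_of[sa[i]];
  }
  return List::create(_["sa"] = sa_out, _["lcp"] = lcp_out,
                      _["read"] = read_out, _["orient"] = orient_out,
                      _["pos"] = pos_out, _["text_length"] = n);
}

// Positional shared k-mer counts per oriented read pair, from maximal
// suffix-array runs with lcp >= k. Within a run every pair of suffixes
// shares the same k-prefix, so cross-read position-pair counts are products
// of per-read occurrence counts. Orientation bookkeeping: '+' counts are
// fwd(a) x fwd(b) occurrences (the rc(a) x rc(b) image of the same hit lies
// in the reverse-complement k-mer's run and is skipped); '-' counts are
// fwd(a) x rc(b) with a < b (the fwd(b) x rc(a) image is likewise skipped).
// Each positional hit is therefore counted exactly once.
// [[Rcpp::export]]
DataFrame count_shared_kmers_cpp(IntegerVector lcp, IntegerVector read,
                                 IntegerVector orient, int k, int nreads,
                                 int max_run = -1) {
  const int n = lcp.size();
  std::unordered_map<uint64_t, double> acc;
  std::unordered_map<int, std::pair<double, double>> occ;  // read -> (fwd, rc)
  int i = 1;
  while (i < n) {
    if (lcp[i] >= k) {
      int start = i - 1;
      while (i < n && lcp[i] >= k) ++i;
      int end = i - 1;  // run covers ranks start..end inclusive
      if (max_run > 0 && end - start + 1 > max_run) continue;
      occ.clear();
      for (int r = start; r <= end; ++r) {
        int rd = read[r];
        if (rd < 0) continue;  // cannot happen inside a run; defensive
        auto& e = occ[rd];
        if (orient[r] == 0) e.first += 1.0; else e.second += 1.0;
      }
      for (auto it1 = occ.begin(); it1 != occ.end(); ++it1) {
        for (auto it2 = occ.begin(); it2 != occ.end(); ++it2) {
          int a = it1->first, b = it2->first;
          if (a >= b) continue;
          double plus = it1->second.first * it2->second.first;
          double minus = it1->second.first * it2->second.second;
          if (plus > 0) {
            uint64_t key = (((uint64_t)a * (uint64_t)nreads + (uint64_t)b) << 1);
            acc[key] += plus;
          }
          if (minus > 0) {
            uint64_t key = (((uint64_t)a * (uint64_t)nreads + (uint64_t)b) << 1) | 1u;
            acc[key] += minus;
          }
        }
      }
    } else {
      ++i;
    }
  }
  const size_t m = acc.size();
  IntegerVector ia(m), ib(m), strand(m);
  NumericVector cnt(m);
  size_t t = 0;
  for (auto& kv : acc) {
    uint64_t key = kv.first;
    strand[t] = (int)(key & 1u);
    uint64_t pair = key >> 1;
    ia[t] = (int)(pair / (uint64_t)nreads);
    ib[t] = (int)(pair % (uint64_t)nreads);
    cnt[t] = kv.second;
    ++t;
  }
  return DataFrame::create(_["a"] = ia, _["b"] = ib, _["strand"] = strand,
                           _["count"] = cnt);
}
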