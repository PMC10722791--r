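#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Restricted Damerau-Levenshtein (optimal string alignment): unit-cost
// insertions, deletions, substitutions and adjacent transpositions, with the
// restriction that no substring is edited twice. This is the distance used
// throughout the mapping cascade.

static int osa_full(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> d0(m + 1), d1(m + 1), d2(m + 1);
  for (int j = 0; j <= m; ++j) d1[j] = j;
  for (int i = 1; i <= n; ++i) {
    d2[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(d2[j - 1] + 1, d1[j] + 1), d1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, d0[j - 2] + 1);
      d2[j] = v;
    }
    std::swap(d0, d1);
    std::swap(d1, d2);
  }
  return d1[m];
}

// Banded variant: returns min(distance, maxd + 1), cheap early exit for the
// candidate-pool search. maxd < 0 means unbounded.
static int osa_bounded(const std::string &a, const std::string &b, int maxd) {
  if (maxd < 0) return osa_full(a, b);
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > maxd) return maxd + 1;
  int d = osa_full(a, b);
  return d > maxd ? maxd + 1 : d;
}

// [[Rcpp::export(name = ".osa_dist")]]
IntegerVector osa_dist_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[i % a.size()]) ||
        CharacterVector::is_na(b[i % b.size()])) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string sa = as<std::string>(a[i % a.size()]);
    std::string sb = as<std::string>(b[i % b.size()]);
    out[i] = osa_full(sa, sb);
  }
  return out;
}

static void char_counts(const std::string &s, int *cnt) {
  std::memset(cnt, 0, 256 * sizeof(int));
  for (unsigned char c : s) cnt[c]++;
}

// Pool pruning + distance in one pass: candidates are kept when
// |len(query) - len(cand)| <= maxd and the character-multiset difference is
// <= 2 * maxd; surviving candidates get a bounded distance, the rest maxd+1.
// [[Rcpp::export(name = ".osa_pool_dist")]]
IntegerVector osa_pool_dist_cpp(std::string query, CharacterVector candidates,
                                int maxd) {
  int qc[256], cc[256];
  char_counts(query, qc);
  const int qlen = query.size();
  IntegerVector out(candidates.size());
  for (R_xlen_t i = 0; i < candidates.size(); ++i) {
    if (CharacterVector::is_na(candidates[i])) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string cand = as<std::string>(candidates[i]);
    int clen = cand.size();
    if (std::abs(clen - qlen) > maxd) {
      out[i] = maxd + 1;
      continue;
    }
    char_counts(cand, cc);
    int diff = 0;
    for (int k = 0; k < 256; ++k) diff += std::abs(qc[k] - cc[k]);
    if (diff > 2 * maxd) {
      out[i] = maxd + 1;
      continue;
    }
    out[i] = osa_bounded(query, cand, maxd);
  }
  return out;
}

// Character-composition filter exposed on its own so candidate_pool() can
// report which names survive pruning before any distance is computed.
// [[Rcpp::export(name = ".charcomp_diff")]]
IntegerVector charcomp_diff_cpp(std::string query, CharacterVector candidates) {
  int qc[256], cc[256];
  char_counts(query, qc);
  IntegerVector out(candidates.size());
  for (R_xlen_t i = 0; i < candidates.size(); ++i) {
    if (CharacterVector::is_na(candidates[i])) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string cand = as<std::string>(candidates[i]);
    char_counts(cand, cc);
    int diff = 0;
    for (int k = 0; k < 256; ++k) diff += std::abs(qc[k] - cc[k]);
    out[i] = diff;
  }
  return out;
}
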