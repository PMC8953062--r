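#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit base codes; anything outside ACGT (incl. N) -> 4 and never matches.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// Best local alignment score under affine gaps, score only.
// Gap of length L costs gap_open + (L - 1) * gap_extend (both penalties
// passed as non-negative costs). Linear memory: rolling rows for H and E,
// column array for F.
// [[Rcpp::export]]
int sw_score_cpp(const std::string& query, const std::string& target,
                 int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  if (m == 0 || n == 0) return 0;

  std::vector<int> q(m), t(n);
  for (int i = 0; i < m; ++i) q[i] = base_code(query[i]);
  for (int j = 0; j < n; ++j) t[j] = base_code(target[j]);

  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), F(n + 1, NEG);
  int best = 0;

  for (int i = 1; i <= m; ++i) {
    int E = NEG;  // horizontal gap state within this row
    Hcur[0] = 0;
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      E = std::max(Hcur[j - 1] - gap_open, E - gap_extend);
      F[j] = std::max(Hprev[j] - gap_open, F[j] - gap_extend);
      int s = (qi == t[j - 1] && qi < 4) ? match : -mismatch;
      int h = Hprev[j - 1] + s;
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// Canonical minimizers: for every w consecutive k-mers take the smallest
// 2-bit-encoded canonical (min of forward and reverse-complement) k-mer
// value; k-mers containing non-ACGT bases are skipped. Returns the sorted
// unique minimizer keys. Requires k <= 15 so keys fit a 32-bit signed int.
// [[Rcpp::export]]
IntegerVector minimizer_keys_cpp(const std::string& seq, int k, int w) {
  const int n = (int) seq.size();
  if (k < 1 || k > 15) stop("k must be in [1, 15]");
  if (w < 1) stop("w must be >= 1");
  if (n < k) return IntegerVector(0);

  const long mask = (1L << (2 * k)) - 1;
  std::vector<long> kmers;
  kmers.reserve(n - k + 1);
  long fwd = 0, rev = 0;
  int valid = 0;  // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c > 3) { valid = 0; fwd = 0; rev = 0; }
    else {
      fwd = ((fwd << 2) | c) & mask;
      rev = (rev >> 2) | ((long)(3 - c) << (2 * (k - 1)));
      ++valid;
    }
    if (i >= k - 1) kmers.push_back(valid >= k ? std::min(fwd, rev) : -1L);
  }

  std::vector<long> keys;
  const int nk = (int) kmers.size();
  for (int start = 0; start + w <= nk; ++start) {
    long mn = -1;
    for (int j = start; j < start + w; ++j) {
      if (kmers[j] >= 0 && (mn < 0 || kmers[j] < mn)) mn = kmers[j];
    }
    if (mn >= 0) keys.push_back(mn);
  }
  std::sort(keys.begin(), keys.end());
  keys.erase(std::unique(keys.begin(), keys.end()), keys.end());

  IntegerVector out((int) keys.size());
  for (size_t i = 0; i < keys.size(); ++i) out[i] = (int) keys[i];
  return out;
}

// Count of shared elements between two sorted unique integer vectors.
// [[Rcpp::export]]
int shared_count_cpp(const IntegerVector& a, const IntegerVector& b) {
  int i = 0, j = 0, n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
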