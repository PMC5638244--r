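#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; -1 marks any non-ACGT character
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Count canonical k-mers (lexicographic min of k-mer and reverse complement)
// over a set of reads. Windows containing a non-ACGT character are rejected
// and tallied. Returns the depth histogram capped at `cap`.
// [[Rcpp::export]]
List kmer_hist_cpp(CharacterVector reads, int k, int cap) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.max_load_factor(0.5f);
  tab.reserve(1 << 22);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);
  long long rejected = 0;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;      // consecutive valid bases ending at i
    long long emitted = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) {
        valid = 0;
        fwd = rev = 0;
        continue;
      }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << rc_shift);
      ++valid;
      if (valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
        ++emitted;
      }
    }
    rejected += (long long)(n - k + 1) - emitted;
  }

  std::vector<double> hist((size_t)cap + 1, 0.0);
  for (auto& kv : tab) {
    uint32_t d = kv.second;
    if ((int)d > cap) d = cap;
    hist[d] += 1.0;
  }
  std::vector<int> depths;
  std::vector<double> counts;
  for (int d = 1; d <= cap; ++d) {
    if (hist[d] > 0) { depths.push_back(d); counts.push_back(hist[d]); }
  }
  return List::create(_["depth"] = wrap(depths),
                      _["count"] = wrap(counts),
                      _["rejected_windows"] = (double)rejected);
}

// Global alignment identity: match +1, mismatch 0, linear gap -1.
// Traceback prefers diagonal, then up (gap in b), then left (gap in a).
// Returns matches / alignment length.
// [[Rcpp::export]]
List nw_identity_cpp(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0); // 1 diag, 2 up, 3 left
  for (int j = 0; j <= m; ++j) { prev[j] = -j; if (j) tb[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    tb[(size_t)i * (m + 1)] = 2;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int up = prev[j] - 1;
      int left = cur[j - 1] - 1;
      int best = diag; uint8_t dir = 1;
      if (up > best) { best = up; dir = 2; }
      if (left > best) { best = left; dir = 3; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  int i = n, j = m;
  long matches = 0, len = 0;
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * (m + 1) + j];
    if (dir == 1) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
    else if (dir == 2) { --i; }
    else { --j; }
    ++len;
  }
  return List::create(_["identity"] = (double)matches / (double)len,
                      _["matches"] = (double)matches,
                      _["alignment_length"] = (double)len,
                      _["score"] = (double)prev[m]);
}
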