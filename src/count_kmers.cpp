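#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

// Greedy left-to-right non-overlapping counting of every observed k-mer.
// For each word independently, an occurrence is selected iff it does not
// overlap the previously selected occurrence of the same word; for
// equal-length intervals this greedy rule attains the maximum number of
// mutually non-overlapping occurrences. Windows containing a non-ACGT
// character never match. Matches never span two input sequences.
//
// Returns words in lexicographic order (2-bit A<C<G<T encoding sorts
// lexicographically), their counts, and the number of valid window
// positions (the overlapping-window total, kept for the alternative
// normalization).
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1) stop("k must be >= 1");
  if (k > 31) stop("k must be <= 31");
  std::unordered_map<uint64_t, double> counts;
  std::unordered_map<uint64_t, long long> last_end;
  const uint64_t mask =
      (k == 31) ? 0x3FFFFFFFFFFFFFFFULL : ((1ULL << (2 * k)) - 1ULL);
  long long offset = 0;
  double n_windows = 0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    const long long n = (long long)std::strlen(str);
    uint64_t code = 0;
    long long run = 0;  // length of current ACGT-only run
    for (long long i = 0; i < n; ++i) {
      int b;
      switch (str[i]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        case 'T': b = 3; break;
        default:  b = -1;
      }
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      if (++run < k) continue;
      n_windows += 1;
      const long long pos = offset + i - k + 1;
      auto it = last_end.find(code);
      if (it == last_end.end()) {
        counts[code] = 1;
        last_end[code] = pos + k - 1;
      } else if (pos > it->second) {
        counts[code] += 1;
        it->second = pos + k - 1;
      }
    }
    offset += n + k;  // gap prevents cross-record overlap bookkeeping
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (const auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  const R_xlen_t m = (R_xlen_t)keys.size();
  CharacterVector words(m);
  NumericVector cnt(m);
  std::string buf(k, 'A');
  static const char alpha[] = "ACGT";
  for (R_xlen_t j = 0; j < m; ++j) {
    uint64_t c = keys[j];
    for (int p = k - 1; p >= 0; --p) {
      buf[p] = alpha[c & 3ULL];
      c >>= 2;
    }
    words[j] = buf;
    cnt[j] = counts[keys[j]];
  }
  return List::create(_["kmer"] = words, _["count"] = cnt,
                      _["n_windows"] = n_windows);
}
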