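#include <Rcpp.h>
#include <set>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 64-bit FNV-1a over k bytes
static inline uint64_t fnv1a(const char* s, int k) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < k; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;
  }
}

// Bottom-s MinHash sketch of the canonical k-mers of a nucleotide sequence.
// Canonical = lexicographic min of the k-mer and its reverse complement;
// windows containing characters other than ACGT (after upper-casing) are
// skipped. Hashes are 64-bit FNV-1a truncated to the top 53 bits so they are
// exactly representable as doubles on the R side. Returned sorted ascending.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(std::string sequence, int kmer_size,
                                int sketch_size) {
  int n = (int)sequence.size();
  if (n < kmer_size) stop("sequence shorter than k");
  for (int i = 0; i < n; ++i) sequence[i] = (char)toupper(sequence[i]);

  std::set<uint64_t> bottom;
  std::string fwd(kmer_size, 'N'), rev(kmer_size, 'N');
  int valid_run = 0;
  for (int i = 0; i < n; ++i) {
    char c = sequence[i];
    if (complement(c) == 0) { valid_run = 0; continue; }
    ++valid_run;
    if (valid_run < kmer_size) continue;
    int start = i - kmer_size + 1;
    for (int j = 0; j < kmer_size; ++j) {
      fwd[j] = sequence[start + j];
      rev[kmer_size - 1 - j] = complement(sequence[start + j]);
    }
    const std::string& canon = (rev < fwd) ? rev : fwd;
    uint64_t h = fnv1a(canon.c_str(), kmer_size) >> 11;  // 53 bits
    if ((int)bottom.size() < sketch_size) {
      bottom.insert(h);
    } else if (h < *bottom.rbegin()) {
      if (bottom.insert(h).second) bottom.erase(std::prev(bottom.end()));
    }
  }
  NumericVector out(bottom.size());
  int j = 0;
  for (std::set<uint64_t>::iterator it = bottom.begin(); it != bottom.end(); ++it)
    out[j++] = (double)*it;
  return out;
}

// All canonical k-mer hashes of a sequence (deduplicated, sorted). Used by
// tests as the exhaustive reference the bottom-s sketch is checked against.
// [[Rcpp::export]]
NumericVector all_kmer_hashes_cpp(std::string sequence, int kmer_size) {
  int n = (int)sequence.size();
  if (n < kmer_size) stop("sequence shorter than k");
  for (int i = 0; i < n; ++i) sequence[i] = (char)toupper(sequence[i]);
  std::set<uint64_t> all;
  std::string fwd(kmer_size, 'N'), rev(kmer_size, 'N');
  int valid_run = 0;
  for (int i = 0; i < n; ++i) {
    char c = sequence[i];
    if (complement(c) == 0) { valid_run = 0; continue; }
    ++valid_run;
    if (valid_run < kmer_size) continue;
    int start = i - kmer_size + 1;
    for (int j = 0; j < kmer_size; ++j) {
      fwd[j] = sequence[start + j];
      rev[kmer_size - 1 - j] = complement(sequence[start + j]);
    }
    const std::string& canon = (rev < fwd) ? rev : fwd;
    all.insert(fnv1a(canon.c_str(), kmer_size) >> 11);
  }
  NumericVector out(all.size());
  int j = 0;
  for (std::set<uint64_t>::iterator it = all.begin(); it != all.end(); ++it)
    out[j++] = (double)*it;
  return out;
}
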