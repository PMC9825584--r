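#include <Rcpp.h>
#include <set>
#include <cstdint>

using namespace Rcpp;

// splitmix64 finalizer; output truncated to the top 53 bits so hash values
// are exactly representable as R doubles
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// 2-bit pack a k-mer starting at seq+pos; returns false if it contains a
// non-ACGT character
static bool pack_kmer(const char* seq, int pos, int k, uint64_t& fwd,
                      uint64_t& rc) {
  fwd = 0; rc = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(seq[pos + i]);
    if (c < 0) return false;
    fwd = (fwd << 2) | (uint64_t)c;
    rc |= ((uint64_t)(3 - c)) << (2 * i);
  }
  return true;
}

static inline double hash53(uint64_t packed, uint64_t seed) {
  return (double)(splitmix64(packed ^ seed) >> 11);
}

// [[Rcpp::export]]
NumericVector minhash_sketch_cpp(CharacterVector seqs, int k, int s,
                                 double seed) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  uint64_t useed = (uint64_t)seed;
  std::set<double> bottom;
  for (int si = 0; si < seqs.size(); ++si) {
    const char* seq = CHAR(STRING_ELT(seqs, si));
    int n = LENGTH(STRING_ELT(seqs, si));
    for (int pos = 0; pos + k <= n; ++pos) {
      uint64_t fwd, rc;
      if (!pack_kmer(seq, pos, k, fwd, rc)) continue;
      uint64_t canon = fwd < rc ? fwd : rc;
      double h = hash53(canon, useed);
      if ((int)bottom.size() < s) {
        bottom.insert(h);
      } else if (h < *bottom.rbegin()) {
        bottom.insert(h);
        if ((int)bottom.size() > s) bottom.erase(std::prev(bottom.end()));
      }
    }
  }
  return NumericVector(bottom.begin(), bottom.end());
}

// hash individual k-mer strings (already canonicalized or not — no
// canonicalization is applied here); NA for k-mers with non-ACGT characters
// [[Rcpp::export]]
NumericVector kmer_hash_cpp(CharacterVector kmers, double seed) {
  uint64_t useed = (uint64_t)seed;
  NumericVector out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int k = LENGTH(STRING_ELT(kmers, i));
    if (k > 32) stop("k must be <= 32");
    uint64_t fwd = 0, rc = 0;
    if (!pack_kmer(s, 0, k, fwd, rc)) {
      out[i] = NA_REAL;
    } else {
      out[i] = hash53(fwd, useed);
    }
  }
  return out;
}
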