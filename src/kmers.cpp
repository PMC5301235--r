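// Low-level k-mer machinery: 2-bit rolling encoders, canonical counting,
// reverse complement, and substitution-error injection for read simulation.
// k is limited to 31 so a k-mer fits one 64-bit word; lexicographic order of
// equal-length ACGT strings coincides with numeric order of the encoding.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t j = 0; j < r.size(); ++j) {
      switch (r[j]) {
      case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
      case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
      case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
      case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
      default: break; // N and friends stay
      }
    }
    out[i] = r;
  }
  return out;
}

// Count canonical k-mers over every ACGT window of every read.
// Windows containing a non-ACGT character are skipped (they break the roll).
// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 16);
  uint64_t fwd = 0, rev = 0;
  long double instances = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    int valid = 0;
    fwd = rev = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
        instances += 1;
      }
    }
  }
  std::vector<std::pair<uint64_t, uint32_t>> items(tab.begin(), tab.end());
  std::sort(items.begin(), items.end());
  R_xlen_t n = items.size();
  CharacterVector kmers(n);
  NumericVector counts(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    kmers[i] = decode_kmer(items[i].first, k);
    counts[i] = items[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = counts,
                      _["instances"] = (double)instances);
}

// Canonical (lexicographic min of self and reverse complement) form of
// fixed-length ACGT strings; NA for strings with other characters.
// [[Rcpp::export(name = ".cpp_canonical")]]
CharacterVector cpp_canonical(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (kmers[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(STRING_ELT(kmers, i));
    int k = LENGTH(STRING_ELT(kmers, i));
    if (k > 31) stop("k-mer longer than 31");
    uint64_t fwd = 0, rev = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
      rev |= ((uint64_t)(3 - b)) << (2 * j);
    }
    if (!ok) { out[i] = NA_STRING; continue; }
    out[i] = decode_kmer(fwd < rev ? fwd : rev, k);
  }
  return out;
}

// Inject i.i.d. substitution errors at `rate` per base, using R's RNG so the
// caller's set.seed() governs reproducibility. Each error replaces the base
// with one of the three other bases, uniformly.
// [[Rcpp::export(name = ".cpp_add_errors")]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  if (rate <= 0) return clone(reads);
  RNGScope scope;
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    int len = s.size();
    int nerr = (int)R::rbinom((double)len, rate);
    if (nerr > 0) {
      for (int e = 0; e < nerr; ++e) {
        int pos = (int)(R::unif_rand() * len);
        if (pos >= len) pos = len - 1;
        int cur = base2bits(s[pos]);
        if (cur < 0) continue;
        int sub = (cur + 1 + (int)(R::unif_rand() * 3)) & 3;
        s[pos] = BITS2BASE[sub];
      }
    }
    out[i] = s;
  }
  return out;
}
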