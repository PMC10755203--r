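// 2-bit packed k-mer kernels for marker discovery, placement and read scanning.
// k is odd and <= 63, so a k-mer fits in a 128-bit code and is never its own
// reverse complement; the canonical form is min(code, rc(code)).
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

typedef unsigned __int128 u128;

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

struct Hash128 {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x;
    uint64_t hi = (uint64_t)(x >> 64);
    uint64_t h = lo ^ (hi * 0x9e3779b97f4a7c15ULL);
    h ^= h >> 30; h *= 0xbf58476d1ce4e5b9ULL;
    h ^= h >> 27; h *= 0x94d049bb133111ebULL;
    h ^= h >> 31;
    return (size_t)h;
  }
};

static inline u128 revcomp_code(u128 code, int k) {
  u128 rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (int)(code & 3));
    code >>= 2;
  }
  return rc;
}

static std::string decode_kmer(u128 code, int k) {
  std::string s(k, 'N');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[(int)(code & 3)];
    code >>= 2;
  }
  return s;
}

static inline u128 encode_kmer(const char* s, int k) {
  u128 code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) stop("k-mer contains a non-ACGT base: %s", std::string(s, k).c_str());
    code = (code << 2) | b;
  }
  return code;
}

typedef std::unordered_map<u128, int, Hash128> KmerMap;

// Roll over one sequence, calling f(canonical_code, fwd_code, position) at
// each valid window; windows touching non-ACGT bases are skipped.
template <typename F>
static void scan_sequence(const char* s, size_t n, int k, F f) {
  if ((size_t)k > n) return;
  u128 mask = (((u128)1) << (2 * k)) - 1;
  u128 fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | b) & mask;
    rev = (rev >> 2) | (((u128)(3 - b)) << (2 * (k - 1)));
    if (++run >= k) {
      u128 canon = fwd < rev ? fwd : rev;
      f(canon, fwd, i + 1 - k);
    }
  }
}

static void check_k(int k) {
  if (k < 3 || k > 63) stop("k must be between 3 and 63");
  if (k % 2 == 0) stop("k must be odd (even k makes canonical form ambiguous)");
}

// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k) {
  check_k(k);
  KmerMap counts;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) continue;
    const char* s = CHAR(seqs[i]);
    scan_sequence(s, strlen(s), k, [&](u128 canon, u128, size_t) {
      ++counts[canon];
    });
  }
  std::vector<u128> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kmer(keys.size());
  IntegerVector count(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kmer[i] = decode_kmer(keys[i], k);
    count[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

static KmerMap build_count_map(CharacterVector kmers, IntegerVector counts, int k) {
  KmerMap m;
  m.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(kmers[i]);
    if ((int)strlen(s) != k) stop("count table k-mer length does not match k");
    m[encode_kmer(s, k)] += counts[i];
  }
  return m;
}

static inline int lookup0(const KmerMap& m, u128 code) {
  auto it = m.find(code);
  return it == m.end() ? 0 : it->second;
}

// Diagnostic-pair discovery: x is A-diagnostic iff abundant in A and rare in
// B, with a one-substitution partner y abundant in B and rare in A. Pairs are
// deduplicated on the canonical pair and reported sorted for determinism.
// [[Rcpp::export]]
DataFrame discover_markers_cpp(CharacterVector kmers_a, IntegerVector counts_a,
                               CharacterVector kmers_b, IntegerVector counts_b,
                               int k, int min_count, int max_other) {
  check_k(k);
  KmerMap ma = build_count_map(kmers_a, counts_a, k);
  KmerMap mb = build_count_map(kmers_b, counts_b, k);

  std::vector<u128> cand;
  for (auto& kv : ma) {
    if (kv.second >= min_count && lookup0(mb, kv.first) <= max_other)
      cand.push_back(kv.first);
  }
  std::sort(cand.begin(), cand.end());

  std::vector<u128> out_a, out_b;
  std::vector<int> out_off, out_ca, out_cab, out_cb, out_cba;
  std::unordered_set<u128, Hash128> seen; // hash of ordered pair

  for (u128 x : cand) {
    int ca = lookup0(ma, x), cab = lookup0(mb, x);
    for (int pos = 0; pos < k; ++pos) {
      int shift = 2 * (k - 1 - pos);
      int cur = (int)((x >> shift) & 3);
      for (int b = 0; b < 4; ++b) {
        if (b == cur) continue;
        u128 y = (x & ~(((u128)3) << shift)) | (((u128)b) << shift);
        u128 yr = revcomp_code(y, k);
        u128 ycan = y < yr ? y : yr;
        if (lookup0(mb, ycan) >= min_count && lookup0(ma, ycan) <= max_other) {
          u128 key = x ^ (ycan * (u128)0x9e3779b97f4a7c15ULL);
          if (!seen.insert(key).second) continue;
          out_a.push_back(x);
          out_b.push_back(ycan);
          out_off.push_back(pos);
          out_ca.push_back(ca);
          out_cab.push_back(cab);
          out_cb.push_back(lookup0(mb, ycan));
          out_cba.push_back(lookup0(ma, ycan));
        }
      }
    }
  }

  R_xlen_t n = out_a.size();
  CharacterVector kmer_a(n), kmer_b(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    kmer_a[i] = decode_kmer(out_a[i], k);
    kmer_b[i] = decode_kmer(out_b[i], k);
  }
  return DataFrame::create(
    _["kmer_a"] = kmer_a, _["kmer_b"] = kmer_b,
    _["snv_offset"] = IntegerVector(out_off.begin(), out_off.end()),
    _["count_a_in_a"] = IntegerVector(out_ca.begin(), out_ca.end()),
    _["count_a_in_b"] = IntegerVector(out_cab.begin(), out_cab.end()),
    _["count_b_in_b"] = IntegerVector(out_cb.begin(), out_cb.end()),
    _["count_b_in_a"] = IntegerVector(out_cba.begin(), out_cba.end()),
    _["stringsAsFactors"] = false);
}

// Exact unique placement of marker k-mers on contigs. Returns, per query
// k-mer, the number of hits (capped at 2) and the first hit's location.
// Strand is "+" when the contig's forward window equals the stored k-mer.
// [[Rcpp::export]]
List place_kmers_cpp(CharacterVector query, CharacterVector contig_seqs, int k) {
  check_k(k);
  std::unordered_map<u128, int, Hash128> idx; // canonical -> query index
  std::vector<u128> stored(query.size());
  for (R_xlen_t i = 0; i < query.size(); ++i) {
    const char* s = CHAR(query[i]);
    if ((int)strlen(s) != k) stop("query k-mer length does not match k");
    u128 code = encode_kmer(s, k);
    stored[i] = code;
    u128 rc = revcomp_code(code, k);
    u128 canon = code < rc ? code : rc;
    if (!idx.emplace(canon, (int)i).second)
      stop("duplicate query k-mer (canonical collision) at index %d", (int)i + 1);
  }
  R_xlen_t nq = query.size();
  IntegerVector n_hits(nq, 0), contig(nq, NA_INTEGER), start(nq, NA_INTEGER);
  CharacterVector strand(nq, NA_STRING);
  for (R_xlen_t c = 0; c < contig_seqs.size(); ++c) {
    const char* s = CHAR(contig_seqs[c]);
    scan_sequence(s, strlen(s), k, [&](u128 canon, u128 fwd, size_t pos) {
      auto it = idx.find(canon);
      if (it == idx.end()) return;
      int i = it->second;
      if (n_hits[i] < 2) ++n_hits[i];
      if (n_hits[i] == 1) {
        contig[i] = (int)c + 1;
        start[i] = (int)pos;
        strand[i] = (fwd == stored[i]) ? "+" : "-";
      }
    });
  }
  return List::create(_["n_hits"] = n_hits, _["contig"] = contig,
                      _["start"] = start, _["strand"] = strand);
}

// Scan reads against a marker lookup (canonical k-mer -> locus, allele) and
// aggregate allele counts per (sample, locus). allele: 0 = parent A, 1 = B.
// [[Rcpp::export]]
DataFrame count_alleles_cpp(CharacterVector reads, IntegerVector sample_idx,
                            CharacterVector marker_kmers, IntegerVector locus_idx,
                            IntegerVector allele, int k) {
  check_k(k);
  if (reads.size() != sample_idx.size())
    stop("reads and sample_idx lengths differ");
  std::unordered_map<u128, std::pair<int,int>, Hash128> lut; // canon -> (locus, allele)
  lut.reserve(marker_kmers.size() * 2);
  for (R_xlen_t i = 0; i < marker_kmers.size(); ++i) {
    const char* s = CHAR(marker_kmers[i]);
    if ((int)strlen(s) != k) stop("marker k-mer length does not match k");
    u128 code = encode_kmer(s, k);
    u128 rc = revcomp_code(code, k);
    u128 canon = code < rc ? code : rc;
    lut[canon] = std::make_pair(locus_idx[i], allele[i]);
  }
  // (sample, locus) -> counts; key packs sample in the high 24 bits
  std::unordered_map<uint64_t, std::pair<int,int>> acc;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING || sample_idx[r] == NA_INTEGER) continue;
    const char* s = CHAR(reads[r]);
    int samp = sample_idx[r];
    scan_sequence(s, strlen(s), k, [&](u128 canon, u128, size_t) {
      auto it = lut.find(canon);
      if (it == lut.end()) return;
      uint64_t key = ((uint64_t)samp << 40) | (uint64_t)it->second.first;
      auto& cc = acc[key];
      if (it->second.second == 0) ++cc.first; else ++cc.second;
    });
  }
  std::vector<uint64_t> keys;
  keys.reserve(acc.size());
  for (auto& kv : acc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t n = keys.size();
  IntegerVector sample(n), locus(n), count_a(n), count_b(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    sample[i] = (int)(keys[i] >> 40);
    locus[i] = (int)(keys[i] & 0xFFFFFFFFFFULL);
    count_a[i] = acc[keys[i]].first;
    count_b[i] = acc[keys[i]].second;
  }
  return DataFrame::create(_["sample"] = sample, _["locus"] = locus,
                           _["count_a"] = count_a, _["count_b"] = count_b,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(seqs[i]);
    size_t n = strlen(s);
    std::string r(n, 'N');
    for (size_t j = 0; j < n; ++j) {
      char c = s[n - 1 - j];
      switch (c) {
      case 'A': r[j] = 'T'; break; case 'C': r[j] = 'G'; break;
      case 'G': r[j] = 'C'; break; case 'T': r[j] = 'A'; break;
      case 'a': r[j] = 't'; break; case 'c': r[j] = 'g'; break;
      case 'g': r[j] = 'c'; break; case 't': r[j] = 'a'; break;
      default: r[j] = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// Substitution errors at a uniform per-base rate, using R's RNG so results
// are reproducible from set.seed(). The erroneous base is one of the other 3.
// [[Rcpp::export]]
CharacterVector inject_errors_cpp(CharacterVector seqs, double error_rate) {
  if (error_rate <= 0) return seqs;
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s(CHAR(seqs[i]));
    int n = (int)s.size();
    int nerr = (int)R::rbinom((double)n, error_rate);
    for (int e = 0; e < nerr; ++e) {
      int pos = (int)(R::unif_rand() * n);
      if (pos >= n) pos = n - 1;
      int b = base2bits(s[pos]);
      if (b < 0) continue;
      int nb = (b + 1 + (int)(R::unif_rand() * 3)) % 4;
      s[pos] = BITS2BASE[nb];
    }
    out[i] = s;
  }
  return out;
}
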