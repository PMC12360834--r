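#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

// splitmix64 finalizer: full-avalanche 64-bit mixer.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

// Hash values are truncated to 53 bits so every value is exactly
// representable in an R double; NA_real_ marks an undefined slot.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline uint64_t hash_code(uint64_t code, uint64_t seed) {
  return mix64(code ^ mix64(seed)) & HASH_MASK;
}

// Seed for (metric slot j, repetition r), derived from the master seed by
// fixed arithmetic so sketches are reproducible across runs and platforms.
static inline uint64_t slot_seed(uint64_t master, int j, int r) {
  return mix64(master ^ mix64(0x100000001b3ULL * (uint64_t)(j + 1) + (uint64_t)r));
}

// metric modes: 0 = identity, 1 = collapse C->T, 2 = collapse G->A
static inline int metric_code(const std::string &m) {
  if (m == "identity") return 0;
  if (m == "ct") return 1;
  if (m == "ga") return 2;
  stop("unknown metric mode '%s' (expected identity/ct/ga)", m.c_str());
  return -1;
}

static inline char collapse_char(char c, int mode) {
  if (mode == 1 && c == 'C') return 'T';
  if (mode == 2 && c == 'G') return 'A';
  return c;
}

// 2-bit code of a base, -1 for non-ACGT
static inline int base2(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// packed 2-bit code of the collapsed image of a k-mer; k <= 31
static inline bool pack_collapsed(const char *s, int k, int mode, uint64_t &out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2(collapse_char(s[i], mode));
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  out = code;
  return true;
}

// Partition digit of a collapsed letter: alphabetical rank within the
// 3-letter collapsed alphabet ({A,G,T} for CT collapse, {A,C,T} for GA).
static inline int partition_digit(char c, int index_mode) {
  char cc = collapse_char(c, index_mode);
  if (index_mode == 1) { // alphabet A,G,T
    if (cc == 'A') return 0; if (cc == 'G') return 1; if (cc == 'T') return 2;
  } else {               // alphabet A,C,T
    if (cc == 'A') return 0; if (cc == 'C') return 1; if (cc == 'T') return 2;
  }
  return -1;
}

static inline int cell_of(const char *s, int kappa, int index_mode) {
  int cell = 0;
  for (int i = 0; i < kappa; ++i) {
    int d = partition_digit(s[i], index_mode);
    if (d < 0) return -1;
    cell = cell * 3 + d;
  }
  return cell;
}

// [[Rcpp::export]]
CharacterVector cpp_shingle(std::string seq, int k) {
  int n = (int)seq.size();
  CharacterVector empty(0);
  if (k < 1) stop("k must be >= 1");
  if (k > 31) stop("k must be <= 31");
  if (n < k) return empty;
  for (int i = 0; i < n; ++i) seq[i] = (char)toupper((unsigned char)seq[i]);
  std::unordered_set<uint64_t> seen;
  std::vector<std::string> out;
  // rolling window; restart after any non-ACGT letter
  uint64_t code = 0, mask = (k == 31) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      if (seen.insert(code).second) out.push_back(seq.substr(i - k + 1, k));
    }
  }
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_collapse(CharacterVector kmers, std::string mode) {
  int m = metric_code(mode);
  int n = kmers.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (base2(s[j]) < 0)
        stop("malformed k-mer '%s': letters must be A/C/G/T", s.c_str());
      s[j] = collapse_char(s[j], m);
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_partition_index(CharacterVector kmers, int kappa, std::string index_mode) {
  int m = metric_code(index_mode);
  if (m == 0) stop("index_mode must be 'ct' or 'ga'");
  int n = kmers.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() < kappa)
      stop("kappa (%d) exceeds k-mer length (%d)", kappa, (int)s.size());
    int cell = cell_of(s.c_str(), kappa, m);
    if (cell < 0) stop("malformed k-mer '%s'", s.c_str());
    out[i] = cell;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_base_hash(CharacterVector kmers, std::string mode, double seed) {
  int m = metric_code(mode);
  uint64_t sd = (uint64_t)seed;
  int n = kmers.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t code;
    if (!pack_collapsed(s.c_str(), (int)s.size(), m, code))
      stop("malformed k-mer '%s'", s.c_str());
    out[i] = (double)hash_code(code, sd);
  }
  return out;
}

// core sketch fill over pre-parsed k-mers
static void sketch_fill(const std::vector<std::string> &kmers,
                        int k, int kappa, const std::vector<int> &metrics,
                        int R, uint64_t master, int index_mode,
                        double *vals, int z) {
  int Delta = (int)metrics.size();
  std::vector<uint64_t> seeds((size_t)Delta * R);
  for (int j = 0; j < Delta; ++j)
    for (int r = 0; r < R; ++r)
      seeds[(size_t)j * R + r] = slot_seed(master, j, r);
  for (const std::string &s : kmers) {
    if ((int)s.size() != k) stop("k-mer '%s' does not have length k=%d", s.c_str(), k);
    int cell = cell_of(s.c_str(), kappa, index_mode);
    if (cell < 0) stop("malformed k-mer '%s'", s.c_str());
    for (int j = 0; j < Delta; ++j) {
      uint64_t code;
      if (!pack_collapsed(s.c_str(), k, metrics[j], code))
        stop("malformed k-mer '%s'", s.c_str());
      for (int r = 0; r < R; ++r) {
        double h = (double)hash_code(code, seeds[(size_t)j * R + r]);
        // layout: cell fastest, then metric, then repetition (R array dims z x Delta x R)
        double *slot = vals + (size_t)cell + (size_t)z * j + (size_t)z * Delta * r;
        if (ISNA(*slot) || h < *slot) *slot = h;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector kmers, int k, int kappa,
                         CharacterVector metrics, int R, double master_seed,
                         std::string index_mode) {
  int im = metric_code(index_mode);
  if (im == 0) stop("index_mode must be 'ct' or 'ga'");
  int Delta = metrics.size();
  std::vector<int> mcodes(Delta);
  for (int j = 0; j < Delta; ++j) mcodes[j] = metric_code(as<std::string>(metrics[j]));
  int z = 1; for (int i = 0; i < kappa; ++i) z *= 3;
  NumericVector out((size_t)z * Delta * R, NA_REAL);
  std::vector<std::string> km(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) km[i] = as<std::string>(kmers[i]);
  sketch_fill(km, k, kappa, mcodes, R, (uint64_t)master_seed, im, REAL(out), z);
  return out;
}

// Sketch many sequences at once (shingling internally); one column per sequence.
// [[Rcpp::export]]
NumericMatrix cpp_sketch_seqs(CharacterVector seqs, int k, int kappa,
                              CharacterVector metrics, int R, double master_seed,
                              std::string index_mode) {
  int im = metric_code(index_mode);
  if (im == 0) stop("index_mode must be 'ct' or 'ga'");
  int Delta = metrics.size();
  std::vector<int> mcodes(Delta);
  for (int j = 0; j < Delta; ++j) mcodes[j] = metric_code(as<std::string>(metrics[j]));
  int z = 1; for (int i = 0; i < kappa; ++i) z *= 3;
  int nslots = z * Delta * R;
  int nseq = seqs.size();
  NumericMatrix out(nslots, nseq);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int s = 0; s < nseq; ++s) {
    std::string sq = as<std::string>(seqs[s]);
    CharacterVector km = cpp_shingle(sq, k);
    std::vector<std::string> kv(km.size());
    for (int i = 0; i < km.size(); ++i) kv[i] = as<std::string>(km[i]);
    sketch_fill(kv, k, kappa, mcodes, R, (uint64_t)master_seed, im,
                REAL(out) + (size_t)s * nslots, z);
  }
  return out;
}
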