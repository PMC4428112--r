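// 2-bit k-mer engine: encoding, canonicalization, target k-mer counting,
// hit-count classification and binary index (de)serialization.
//
// K-mer codes cross the R boundary as decimal strings because R has no
// exact 64-bit integer type (doubles lose exactness above 2^53, i.e. k > 26).
// All inner loops work on uint64_t.

#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <cstring>
#include <cstdio>
#include <cerrno>
#include <fstream>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// A=0, C=1, G=2, T=3; U treated as T; anything else (N, IUPAC) rejected.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline uint64_t canonical_code(uint64_t code, int k) {
  uint64_t rc = revcomp_code(code, k);
  return rc < code ? rc : code;
}

static inline uint64_t kmask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

static void check_k(int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32 (got %d)", k);
}

// decimal parse by hand (also avoids the glibc-2.38-only __isoc23_strtoull
// that newer toolchains emit for strtoull)
static uint64_t parse_code(const char* s, int k) {
  if (*s == '\0') stop("empty k-mer code string");
  uint64_t v = 0;
  for (const char* p = s; *p; ++p) {
    if (*p < '0' || *p > '9')
      stop("invalid k-mer code '%s': not an unsigned decimal integer", s);
    uint64_t d = (uint64_t)(*p - '0');
    if (v > (UINT64_MAX - d) / 10ULL)
      stop("k-mer code '%s' overflows 64 bits", s);
    v = v * 10ULL + d;
  }
  // 4^k bound; for k = 32 every uint64 is valid
  if (k < 32 && v > kmask(k))
    stop("k-mer code '%s' out of range for k = %d", s, k);
  return (uint64_t)v;
}

static std::string format_code(uint64_t v) {
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", (unsigned long long)v);
  return std::string(buf);
}

// [[Rcpp::export]]
CharacterVector cpp_encode(CharacterVector kmers) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    int k = (int)std::strlen(s);
    check_k(k);
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0)
        stop("ambiguous or invalid base '%c' at position %d of k-mer '%s'",
             s[j], j + 1, s);
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = format_code(code);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(CharacterVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::string s(k, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = parse_code(CHAR(STRING_ELT(codes, i)), k);
    for (int j = k - 1; j >= 0; --j) {
      s[j] = BITS2BASE[code & 3ULL];
      code >>= 2;
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = format_code(
        revcomp_code(parse_code(CHAR(STRING_ELT(codes, i)), k), k));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector codes, int k) {
  check_k(k);
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = format_code(
        canonical_code(parse_code(CHAR(STRING_ELT(codes, i)), k), k));
  return out;
}

// Rolling scan of one sequence; calls f(pos0based, canonicalCode) for every
// window of k consecutive unambiguous bases.
template <typename F>
static void scan_windows(const char* s, int len, int k, F f) {
  uint64_t code = 0, mask = kmask(k);
  int run = 0;  // length of current unambiguous run ending at i
  for (int i = 0; i < len; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {
      run = 0;
      code = 0;
      continue;
    }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(i - k + 1, canonical_code(code, k));
  }
}

static inline int count_valid_windows(const char* s, int len, int k) {
  int n = 0;
  scan_windows(s, len, k, [&](int, uint64_t) { ++n; });
  return n;
}

// [[Rcpp::export]]
List cpp_extract(std::string seq, int k) {
  check_k(k);
  std::vector<int> pos;
  std::vector<std::string> code;
  scan_windows(seq.c_str(), (int)seq.size(), k, [&](int p, uint64_t c) {
    pos.push_back(p);
    code.push_back(format_code(c));
  });
  return List::create(_["pos"] = wrap(pos), _["code"] = wrap(code));
}

// --- target k-mer counting -------------------------------------------------

struct RawEntry {
  int32_t first_t;  // first target seen containing the k-mer
  int32_t last_t;   // last distinct target seen (== second when n_targets == 2)
  int32_t n_targets;
  uint32_t occ;
};

// Sequences MUST be grouped by target id (the R wrapper sorts); distinct
// targets are then countable from the last-seen id alone, and for
// n_targets == 2 (first_t, last_t) identify the pair (centromere rule).
// target_ids are 0-based here.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, IntegerVector target_ids, int k) {
  check_k(k);
  if (seqs.size() == 0) stop("no target sequences given");
  if (seqs.size() != target_ids.size())
    stop("seqs and target_ids lengths differ");
  std::unordered_map<uint64_t, RawEntry> tab;
  tab.reserve(1 << 16);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int32_t t = target_ids[i];
    if (i > 0 && t < target_ids[i - 1])
      stop("sequences must be grouped by target id");
    const char* s = CHAR(STRING_ELT(seqs, i));
    scan_windows(s, (int)std::strlen(s), k, [&](int, uint64_t c) {
      auto it = tab.find(c);
      if (it == tab.end()) {
        tab.emplace(c, RawEntry{t, t, 1, 1});
      } else {
        RawEntry& e = it->second;
        e.occ++;
        if (e.last_t != t) {
          e.n_targets++;
          e.last_t = t;
        }
      }
    });
  }
  std::vector<std::pair<uint64_t, RawEntry>> v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end(),
            [](const std::pair<uint64_t, RawEntry>& a,
               const std::pair<uint64_t, RawEntry>& b) {
              return a.first < b.first;
            });
  R_xlen_t n = (R_xlen_t)v.size();
  CharacterVector code(n);
  IntegerVector first_t(n), last_t(n), n_targets(n), occ(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    code[i] = format_code(v[i].first);
    first_t[i] = v[i].second.first_t + 1;  // back to 1-based for R
    last_t[i] = v[i].second.last_t + 1;
    n_targets[i] = v[i].second.n_targets;
    occ[i] = (int)v[i].second.occ;
  }
  return List::create(_["code"] = code, _["first_target"] = first_t,
                      _["last_target"] = last_t, _["n_targets"] = n_targets,
                      _["occurrences"] = occ);
}

// --- classification --------------------------------------------------------

// modes: 0 = full scoring (also used by light), 1 = default (early stop),
//        2 = express (non-overlapping windows, first hit wins)
// [[Rcpp::export]]
List cpp_classify(CharacterVector objects, CharacterVector index_codes,
                  IntegerVector index_targets, int k, int n_targets, int mode,
                  bool return_hits) {
  check_k(k);
  std::unordered_map<uint64_t, int32_t> idx;
  idx.reserve((size_t)index_codes.size() * 2 + 16);
  for (R_xlen_t i = 0; i < index_codes.size(); ++i)
    idx.emplace(parse_code(CHAR(STRING_ELT(index_codes, i)), k),
                index_targets[i] - 1);

  R_xlen_t nobj = objects.size();
  IntegerVector n_kmers(nobj), h1(nobj), h2(nobj), best(nobj);
  LogicalVector tie(nobj);
  IntegerMatrix hits_mat =
      return_hits ? IntegerMatrix(nobj, n_targets) : IntegerMatrix(0, 0);

  std::vector<int> hits(n_targets);
  for (R_xlen_t i = 0; i < nobj; ++i) {
    const char* s = CHAR(STRING_ELT(objects, i));
    int len = (int)std::strlen(s);
    std::fill(hits.begin(), hits.end(), 0);
    int nk = count_valid_windows(s, len, k);
    n_kmers[i] = nk;

    int b = -1, hh1 = 0, hh2 = 0;
    bool tied = false;

    if (mode == 2) {
      // express: query windows starting at 0, k, 2k, ...; first hit assigns
      for (int p = 0; p + k <= len; p += k) {
        uint64_t code = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int bb = base2bits(s[p + j]);
          if (bb < 0) { ok = false; break; }
          code = (code << 2) | (uint64_t)bb;
        }
        if (!ok) continue;
        auto it = idx.find(canonical_code(code, k));
        if (it != idx.end()) {
          b = it->second;
          hh1 = 1;
          break;
        }
      }
    } else {
      int stop_at = (mode == 1) ? (nk + 1) / 2 : -1;  // ceil(nk / 2)
      bool stopped = false;
      scan_windows(s, len, k, [&](int, uint64_t c) {
        if (stopped) return;
        auto it = idx.find(c);
        if (it != idx.end()) {
          int t = it->second;
          hits[t]++;
          if (stop_at > 0 && hits[t] >= stop_at) stopped = true;
        }
      });
      for (int t = 0; t < n_targets; ++t) {
        int h = hits[t];
        if (h > hh1) {
          hh2 = hh1;
          hh1 = h;
          b = t;
          tied = false;
        } else if (h > 0 && h == hh1) {
          hh2 = std::max(hh2, h);
          tied = true;  // b keeps the smaller target id
        } else if (h > hh2) {
          hh2 = h;
        }
      }
      if (hh1 == 0) b = -1;
      if (return_hits)
        for (int t = 0; t < n_targets; ++t) hits_mat(i, t) = hits[t];
    }

    h1[i] = hh1;
    h2[i] = hh2;
    best[i] = (b < 0) ? NA_INTEGER : b + 1;
    tie[i] = tied;
  }

  List out = List::create(_["n_kmers"] = n_kmers, _["h1"] = h1, _["h2"] = h2,
                          _["target"] = best, _["tie"] = tie);
  if (return_hits) out["hits"] = hits_mat;
  return out;
}

// --- binary index file -----------------------------------------------------

static const char INDEX_MAGIC[8] = {'D', 'K', 'M', 'E', 'R', 'I', 'X', '1'};
static const uint32_t INDEX_VERSION = 1;

template <typename T>
static void wr(std::ofstream& f, T v) {
  f.write(reinterpret_cast<const char*>(&v), sizeof(T));
}
static void wr_str(std::ofstream& f, const std::string& s) {
  wr<uint64_t>(f, (uint64_t)s.size());
  f.write(s.data(), (std::streamsize)s.size());
}
template <typename T>
static T rd(std::ifstream& f, const char* what) {
  T v;
  f.read(reinterpret_cast<char*>(&v), sizeof(T));
  if (!f) stop("corrupt or truncated index file while reading %s", what);
  return v;
}
static std::string rd_str(std::ifstream& f, const char* what) {
  uint64_t n = rd<uint64_t>(f, what);
  if (n > (1ULL << 33)) stop("corrupt index file: absurd string length");
  std::string s(n, '\0');
  f.read(&s[0], (std::streamsize)n);
  if (!f) stop("corrupt or truncated index file while reading %s", what);
  return s;
}

// [[Rcpp::export]]
void cpp_save_index(std::string path, int k, int min_occurrence,
                    int sampling,  // 0 none, 1 half, 2 light_stride
                    CharacterVector labels, CharacterVector codes,
                    IntegerVector targets, IntegerVector occurrences,
                    CharacterVector seq_ids, IntegerVector seq_targets,
                    CharacterVector seqs) {
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  f.write(INDEX_MAGIC, 8);
  wr<uint32_t>(f, INDEX_VERSION);
  wr<uint32_t>(f, (uint32_t)k);
  wr<uint32_t>(f, (uint32_t)min_occurrence);
  wr<uint8_t>(f, (uint8_t)sampling);
  wr<uint32_t>(f, (uint32_t)labels.size());
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    wr_str(f, std::string(CHAR(STRING_ELT(labels, i))));
  wr<uint64_t>(f, (uint64_t)codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    wr<uint64_t>(f, parse_code(CHAR(STRING_ELT(codes, i)), k));
    wr<uint32_t>(f, (uint32_t)targets[i]);
    wr<uint32_t>(f, (uint32_t)occurrences[i]);
  }
  wr<uint32_t>(f, (uint32_t)seq_ids.size());
  for (R_xlen_t i = 0; i < seq_ids.size(); ++i) {
    wr_str(f, std::string(CHAR(STRING_ELT(seq_ids, i))));
    wr<uint32_t>(f, (uint32_t)seq_targets[i]);
    wr_str(f, std::string(CHAR(STRING_ELT(seqs, i))));
  }
  if (!f) stop("write failure on '%s'", path.c_str());
}

// [[Rcpp::export]]
List cpp_load_index(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open index file '%s'", path.c_str());
  char magic[8];
  f.read(magic, 8);
  if (!f || std::memcmp(magic, INDEX_MAGIC, 8) != 0)
    stop("'%s' is not a diskmer index file (bad magic)", path.c_str());
  uint32_t version = rd<uint32_t>(f, "version");
  if (version != INDEX_VERSION)
    stop("unsupported index format version %u (expected %u)", version,
         INDEX_VERSION);
  int k = (int)rd<uint32_t>(f, "k");
  check_k(k);
  int min_occ = (int)rd<uint32_t>(f, "min_occurrence");
  int sampling = (int)rd<uint8_t>(f, "sampling");
  uint32_t nlab = rd<uint32_t>(f, "label count");
  CharacterVector labels(nlab);
  for (uint32_t i = 0; i < nlab; ++i) labels[i] = rd_str(f, "label");
  uint64_t nent = rd<uint64_t>(f, "entry count");
  CharacterVector codes(nent);
  IntegerVector targets(nent), occ(nent);
  for (uint64_t i = 0; i < nent; ++i) {
    codes[i] = format_code(rd<uint64_t>(f, "k-mer code"));
    targets[i] = (int)rd<uint32_t>(f, "target id");
    occ[i] = (int)rd<uint32_t>(f, "occurrence count");
  }
  uint32_t nseq = rd<uint32_t>(f, "sequence count");
  CharacterVector seq_ids(nseq), seqs(nseq);
  IntegerVector seq_targets(nseq);
  for (uint32_t i = 0; i < nseq; ++i) {
    seq_ids[i] = rd_str(f, "sequence id");
    seq_targets[i] = (int)rd<uint32_t>(f, "sequence target id");
    seqs[i] = rd_str(f, "sequence");
  }
  return List::create(
      _["k"] = k, _["min_occurrence"] = min_occ, _["sampling"] = sampling,
      _["labels"] = labels, _["code"] = codes, _["target_id"] = targets,
      _["occurrences"] = occ, _["seq_ids"] = seq_ids,
      _["seq_targets"] = seq_targets, _["seqs"] = seqs);
}
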