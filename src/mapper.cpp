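#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <memory>
#include <vector>
using namespace Rcpp;

// All-hits Hamming mapper.
//
// Semantics: a hit is (ref, start, strand, mm) with mm = Hamming distance
// between the read (or its reverse complement for strand '-') and
// ref[start, start+len).  N (or any non-ACGT code) never matches anything,
// including another N.  Reads longer than a reference simply have no hits
// on it.
//
// Strategy: references are 2-bit-encodable; a sorted k-mer seed index is
// built when the reference set is large enough to repay it.  Exact matching
// uses one seed per read orientation; mismatch-tolerant matching partitions
// the read into (max_mm + 1) contiguous parts (pigeonhole: at least one
// part of any qualifying alignment is mismatch-free) and seeds on each
// part's k-prefix.  Reads too short for that fall back to a direct scan.

static const uint8_t CODE_N = 4;

static inline uint8_t encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return CODE_N;
  }
}

static std::vector<uint8_t> encode_seq(const char *s, size_t n) {
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = encode_base(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
  size_t n = v.size();
  std::vector<uint8_t> r(n);
  for (size_t i = 0; i < n; ++i) {
    uint8_t b = v[n - 1 - i];
    r[i] = (b < 4) ? (3 - b) : CODE_N;
  }
  return r;
}

// mismatches between read and ref[start, ...), early exit above cap
static inline int hamming_at(const std::vector<uint8_t> &read,
                             const std::vector<uint8_t> &ref,
                             size_t start, int cap) {
  int mm = 0;
  size_t L = read.size();
  for (size_t i = 0; i < L; ++i) {
    uint8_t a = read[i], b = ref[start + i];
    if (a != b || a == CODE_N) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Hit {
  int ref;      // 0-based reference index
  int start;    // 0-based offset
  int strand;   // 0 = '+', 1 = '-'
  int mm;
};

static void scan_ref(const std::vector<uint8_t> &read,
                     const std::vector<uint8_t> &ref,
                     int ref_idx, int strand, int max_mm,
                     std::vector<Hit> &out) {
  size_t L = read.size(), R = ref.size();
  if (L == 0 || L > R) return;
  for (size_t s = 0; s + L <= R; ++s) {
    int mm = hamming_at(read, ref, s, max_mm);
    if (mm <= max_mm) out.push_back({ref_idx, (int)s, strand, mm});
  }
}

// Packed index entry: kmer (<=24 bits) | ref (12 bits) | pos (28 bits)
static inline uint64_t pack_entry(uint64_t kmer, uint64_t ref, uint64_t pos) {
  return (kmer << 40) | (ref << 28) | pos;
}

class SeedIndex {
public:
  int k;
  std::vector<uint64_t> entries;  // sorted

  SeedIndex(const std::vector<std::vector<uint8_t>> &refs, int k_) : k(k_) {
    size_t total = 0;
    for (auto &r : refs) total += (r.size() >= (size_t)k) ? r.size() - k + 1 : 0;
    entries.reserve(total);
    for (size_t ri = 0; ri < refs.size(); ++ri) {
      const std::vector<uint8_t> &r = refs[ri];
      if (r.size() < (size_t)k) continue;
      uint64_t kmer = 0, mask = ((uint64_t)1 << (2 * k)) - 1;
      int valid = 0;  // run length of non-N bases ending here
      for (size_t i = 0; i < r.size(); ++i) {
        if (r[i] == CODE_N) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | r[i]) & mask;
        if (++valid >= k)
          entries.push_back(pack_entry(kmer, ri, i - k + 1));
      }
    }
    std::sort(entries.begin(), entries.end());
  }

  // positions of kmer as (ref, pos); appends to out
  void lookup(uint64_t kmer, std::vector<std::pair<int,int>> &out) const {
    uint64_t lo = kmer << 40, hi = (kmer + 1) << 40;
    auto it = std::lower_bound(entries.begin(), entries.end(), lo);
    for (; it != entries.end() && *it < hi; ++it) {
      out.push_back({(int)((*it >> 28) & 0xFFF), (int)(*it & 0xFFFFFFFULL)});
    }
  }
};

// seed-and-verify one read orientation against indexed refs
static void seeded_search(const std::vector<uint8_t> &read,
                          const std::vector<std::vector<uint8_t>> &refs,
                          const SeedIndex &idx, int strand, int max_mm,
                          std::vector<Hit> &out) {
  int L = (int)read.size();
  int nparts = max_mm + 1;
  int partlen = L / nparts;
  std::vector<std::pair<int,int>> cand;
  std::vector<std::pair<int,int>> seen;  // (ref, start) candidates tried
  for (int p = 0; p < nparts; ++p) {
    int off = p * partlen;
    // build seed kmer at read[off, off+k)
    uint64_t kmer = 0;
    bool ok = true;
    for (int i = 0; i < idx.k; ++i) {
      uint8_t b = read[off + i];
      if (b == CODE_N) { ok = false; break; }
      kmer = (kmer << 2) | b;
    }
    if (!ok) continue;  // seed with N can never match (N matches nothing)
    cand.clear();
    idx.lookup(kmer, cand);
    for (auto &c : cand) {
      int start = c.second - off;
      const std::vector<uint8_t> &ref = refs[c.first];
      if (start < 0 || (size_t)(start + L) > ref.size()) continue;
      std::pair<int,int> key(c.first, start);
      if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
      seen.push_back(key);
      int mm = hamming_at(read, ref, start, max_mm);
      if (mm <= max_mm) out.push_back({c.first, start, strand, mm});
    }
  }
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector refs,
                        int max_mm, bool report_all) {
  int n_reads = reads.size(), n_refs = refs.size();
  std::vector<std::vector<uint8_t>> R(n_refs);
  size_t total_ref = 0, max_ref_len = 0;
  for (int i = 0; i < n_refs; ++i) {
    const char *s = CHAR(STRING_ELT(refs, i));
    R[i] = encode_seq(s, LENGTH(STRING_ELT(refs, i)));
    total_ref += R[i].size();
    max_ref_len = std::max(max_ref_len, R[i].size());
  }

  int k = (max_mm == 0) ? 12 : 8;
  // the packed index carries ref in 12 bits and pos in 28
  bool use_index = total_ref > 10000 && n_refs <= 4096 &&
                   max_ref_len < ((size_t)1 << 28);
  std::unique_ptr<SeedIndex> idx;
  if (use_index) idx.reset(new SeedIndex(R, k));

  std::vector<int> o_read, o_ref, o_start, o_strand, o_mm;
  std::vector<Hit> hits;
  for (int i = 0; i < n_reads; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    std::vector<uint8_t> fwd = encode_seq(s, LENGTH(STRING_ELT(reads, i)));
    std::vector<uint8_t> rev = revcomp(fwd);
    int L = (int)fwd.size();
    bool has_n = std::find(fwd.begin(), fwd.end(), CODE_N) != fwd.end();
    int partlen = L / (max_mm + 1);
    bool can_seed = use_index && !has_n && partlen >= k;

    hits.clear();
    if (can_seed) {
      seeded_search(fwd, R, *idx, 0, max_mm, hits);
      seeded_search(rev, R, *idx, 1, max_mm, hits);
    } else {
      for (int r = 0; r < n_refs; ++r) {
        scan_ref(fwd, R[r], r, 0, max_mm, hits);
        scan_ref(rev, R[r], r, 1, max_mm, hits);
      }
    }
    if (hits.empty()) continue;
    int best = max_mm;
    if (!report_all) {
      best = hits[0].mm;
      for (auto &h : hits) best = std::min(best, h.mm);
    }
    // deterministic order: ref, start, strand (+ before -)
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    for (auto &h : hits) {
      if (!report_all && h.mm > best) continue;
      o_read.push_back(i + 1);
      o_ref.push_back(h.ref + 1);
      o_start.push_back(h.start);
      o_strand.push_back(h.strand);
      o_mm.push_back(h.mm);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["ref"] = o_ref, _["start"] = o_start,
    _["strand"] = o_strand, _["mismatches"] = o_mm);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  static const char *letters = "ACGTN";
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    int L = LENGTH(STRING_ELT(x, i));
    std::string r(L, 'N');
    for (int j = 0; j < L; ++j) {
      uint8_t b = encode_base(s[L - 1 - j]);
      r[j] = letters[(b < 4) ? (3 - b) : 4];
    }
    out[i] = r;
  }
  return out;
}
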