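#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// All-hits near-exact (Hamming) placement of short sequences on a set of
// scaffolds. Pigeonhole seed index: with <= mm mismatches, at least one of
// mm+1 disjoint k-mers of the query matches the subject exactly. Queries too
// short to carry mm+1 disjoint seeds (or containing N) fall back to a brute
// scan, so sensitivity is exact for every query.

static const int KLEN = 10;
static const uint32_t NBUCKET = 1u << (2 * KLEN);  // 4^10

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N or other: never matches anything
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

struct Genome {
  std::vector<int8_t> seq;        // concatenated encoded scaffolds
  std::vector<int> scaf_start;    // offset of each scaffold in seq
  std::vector<int> scaf_len;
  // bucketed seed index over the concatenation
  std::vector<int> bucket_off;    // NBUCKET+1 offsets into pos
  std::vector<int> pos;           // global positions sorted by bucket
};

static void build_genome(const CharacterVector& scaffolds, Genome& g) {
  int n = scaffolds.size();
  size_t total = 0;
  for (int i = 0; i < n; ++i) total += LENGTH(STRING_ELT(scaffolds, i));
  g.seq.reserve(total);
  g.scaf_start.resize(n);
  g.scaf_len.resize(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(scaffolds, i));
    int L = LENGTH(STRING_ELT(scaffolds, i));
    g.scaf_start[i] = (int)g.seq.size();
    g.scaf_len[i] = L;
    for (int j = 0; j < L; ++j) g.seq.push_back((int8_t)enc(s[j]));
  }
  // count k-mers per bucket (skip k-mers containing N, and k-mers spanning
  // scaffold boundaries)
  std::vector<int> cnt(NBUCKET + 1, 0);
  for (int i = 0; i < n; ++i) {
    int st = g.scaf_start[i], L = g.scaf_len[i];
    if (L < KLEN) continue;
    uint32_t key = 0; int bad = 0;
    for (int j = 0; j < L; ++j) {
      int8_t b = g.seq[st + j];
      key = ((key << 2) | (b & 3)) & (NBUCKET - 1);
      bad = (b == 4) ? KLEN : (bad > 0 ? bad - 1 : 0);
      if (j >= KLEN - 1 && bad == 0) cnt[key]++;
    }
  }
  g.bucket_off.assign(NBUCKET + 1, 0);
  for (uint32_t b = 0; b < NBUCKET; ++b) g.bucket_off[b + 1] = g.bucket_off[b] + cnt[b];
  g.pos.resize(g.bucket_off[NBUCKET]);
  std::vector<int> fill(NBUCKET, 0);
  for (int i = 0; i < n; ++i) {
    int st = g.scaf_start[i], L = g.scaf_len[i];
    if (L < KLEN) continue;
    uint32_t key = 0; int bad = 0;
    for (int j = 0; j < L; ++j) {
      int8_t b = g.seq[st + j];
      key = ((key << 2) | (b & 3)) & (NBUCKET - 1);
      bad = (b == 4) ? KLEN : (bad > 0 ? bad - 1 : 0);
      if (j >= KLEN - 1 && bad == 0) {
        g.pos[g.bucket_off[key] + fill[key]++] = st + j - (KLEN - 1);
      }
    }
  }
}

// Hamming distance with early exit
static inline int ham(const int8_t* a, const int8_t* q, int L, int mmax) {
  int mm = 0;
  for (int j = 0; j < L; ++j) {
    if (a[j] != q[j] || q[j] == 4) {
      if (++mm > mmax) return mm;
    }
  }
  return mm;
}

struct Hit { int scaf; int start; int strand; int mm; };

static void scan_one(const Genome& g, const std::vector<int8_t>& q, int mmax,
                     int strand, std::vector<Hit>& out) {
  int L = (int)q.size();
  bool hasN = false;
  for (int j = 0; j < L; ++j) if (q[j] == 4) { hasN = true; break; }
  int nseed = mmax + 1;
  bool brute = hasN || L < KLEN || nseed * KLEN > L;
  int nscaf = (int)g.scaf_start.size();
  if (brute) {
    for (int s = 0; s < nscaf; ++s) {
      int st = g.scaf_start[s], SL = g.scaf_len[s];
      for (int p = 0; p + L <= SL; ++p) {
        int mm = ham(&g.seq[st + p], q.data(), L, mmax);
        if (mm <= mmax) out.push_back({s, p, strand, mm});
      }
    }
    return;
  }
  std::vector<int> cand;
  for (int sd = 0; sd < nseed; ++sd) {
    int off = sd * KLEN;
    uint32_t key = 0;
    for (int j = 0; j < KLEN; ++j) key = (key << 2) | (q[off + j] & 3);
    for (int t = g.bucket_off[key]; t < g.bucket_off[key + 1]; ++t) {
      int gp = g.pos[t] - off;
      cand.push_back(gp);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  // map global position to scaffold by binary search
  for (int gp : cand) {
    if (gp < 0) continue;
    int s = (int)(std::upper_bound(g.scaf_start.begin(), g.scaf_start.end(), gp)
                  - g.scaf_start.begin()) - 1;
    int p = gp - g.scaf_start[s];
    if (p + L > g.scaf_len[s]) continue;
    int mm = ham(&g.seq[gp], q.data(), L, mmax);
    if (mm <= mmax) out.push_back({s, p, strand, mm});
  }
}

// [[Rcpp::export]]
DataFrame cpp_place_reads(CharacterVector scaffolds, CharacterVector queries,
                          IntegerVector max_mm) {
  Genome g;
  build_genome(scaffolds, g);
  std::vector<int> r_read, r_scaf, r_start, r_strand, r_mm;
  int nq = queries.size();
  std::vector<Hit> hits;
  for (int i = 0; i < nq; ++i) {
    const char* s = CHAR(STRING_ELT(queries, i));
    int L = LENGTH(STRING_ELT(queries, i));
    std::vector<int8_t> fwd(L), rev(L);
    for (int j = 0; j < L; ++j) fwd[j] = (int8_t)enc(s[j]);
    for (int j = 0; j < L; ++j) rev[j] = (int8_t)enc(comp(s[L - 1 - j]));
    hits.clear();
    scan_one(g, fwd, max_mm[i], 1, hits);
    scan_one(g, rev, max_mm[i], -1, hits);
    for (const Hit& h : hits) {
      r_read.push_back(i + 1);
      r_scaf.push_back(h.scaf + 1);
      r_start.push_back(h.start);
      r_strand.push_back(h.strand);
      r_mm.push_back(h.mm);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
    _["query"] = r_read, _["scaffold"] = r_scaf, _["start"] = r_start,
    _["strand"] = r_strand, _["mismatches"] = r_mm);
}
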