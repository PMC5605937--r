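// Seed-and-extend ungapped short-read mapper.
//
// Query domain: 16-23 nt host remnants and 20 nt read-2 prefixes under a
// >= 95% identity contract, so at most floor(L * 0.05) = 0 or 1 substitutions
// are admissible and ungapped extension is exact.  Candidate generation uses
// internal 8-mer seeds with pigeonhole chunking: the query is split into
// (m+1) contiguous chunks (m = tolerated mismatches); any hit with <= m
// mismatches leaves at least one chunk exact, whose leading 8-mer is then an
// exact seed.  This is lossless for the length/identity domain above, which
// a fixed longer seed (e.g. 12) is not.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const int SEED_K = 8;
static const uint32_t NBUCKETS = 1u << (2 * SEED_K); // 4^8 = 65536

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1; // N or anything else
  }
}

struct SeedIndex {
  // counting-sort layout: bucket b occupies pos[starts[b] .. starts[b+1])
  std::vector<int> starts;
  std::vector<int> pos;
  int n;        // genome length
  bool circular;
  std::string ext; // genome plus wrap pad (circular) for linear extension
};

static void build_seed_index(const std::string& g, bool circular, int pad,
                             SeedIndex& idx) {
  int n = (int)g.size();
  idx.n = n;
  idx.circular = circular;
  idx.ext = g;
  if (circular) idx.ext += g.substr(0, std::min(n, pad));
  int last = circular ? n : n - SEED_K + 1;
  if (last < 0) last = 0;
  std::vector<uint32_t> codes(last, UINT32_MAX);
  // rolling 2-bit code; reset on N
  uint32_t code = 0;
  int run = 0;
  const uint32_t mask = NBUCKETS - 1;
  for (int i = 0; i < (int)idx.ext.size(); ++i) {
    int b = base_code(idx.ext[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)b) & mask;
    if (++run >= SEED_K) {
      int start = i - SEED_K + 1;
      if (start < last) codes[start] = code;
    }
  }
  std::vector<int> cnt(NBUCKETS + 1, 0);
  for (int i = 0; i < last; ++i)
    if (codes[i] != UINT32_MAX) cnt[codes[i] + 1]++;
  for (uint32_t b = 0; b < NBUCKETS; ++b) cnt[b + 1] += cnt[b];
  idx.starts = cnt;
  idx.pos.assign(cnt[NBUCKETS], 0);
  std::vector<int> fill(idx.starts.begin(), idx.starts.end() - 1);
  for (int i = 0; i < last; ++i)
    if (codes[i] != UINT32_MAX) idx.pos[fill[codes[i]]++] = i;
}

static inline bool seed_code_of(const std::string& q, int off, uint32_t& code) {
  code = 0;
  for (int j = 0; j < SEED_K; ++j) {
    int b = base_code(q[off + j]);
    if (b < 0) return false;
    code = (code << 2) | (uint32_t)b;
  }
  return true;
}

// count mismatches of q against genome at (possibly wrapped) position p,
// bailing out past `maxmm`; N in the genome counts as mismatch
static inline int count_mm(const SeedIndex& idx, const std::string& q, int p,
                           int maxmm) {
  int L = (int)q.size();
  int mm = 0;
  if (!idx.circular || p + L <= (int)idx.ext.size()) {
    const char* g = idx.ext.data() + p;
    for (int j = 0; j < L; ++j) {
      if (g[j] != q[j] || g[j] == 'N') { if (++mm > maxmm) return mm; }
    }
  } else {
    for (int j = 0; j < L; ++j) {
      char c = idx.ext[(p + j) % idx.n];
      if (c != q[j] || c == 'N') { if (++mm > maxmm) return mm; }
    }
  }
  return mm;
}

struct Hit { int fwd_left; bool minus; int mm; };

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// all hits of `q` (already oriented) against the forward genome
static void scan_orientation(const SeedIndex& idx, const std::string& q,
                             int maxmm, bool minus, std::vector<Hit>& out) {
  int L = (int)q.size();
  if (L < SEED_K) return;
  int nchunk = maxmm + 1;
  std::vector<int> cand;
  for (int c = 0; c < nchunk; ++c) {
    // chunk c covers [c*L/nchunk, (c+1)*L/nchunk); length >= 8 for L >= 16
    int off = (int)((long long)c * L / nchunk);
    if (off + SEED_K > L) off = L - SEED_K;
    uint32_t code;
    if (!seed_code_of(q, off, code)) continue;
    for (int t = idx.starts[code]; t < idx.starts[code + 1]; ++t) {
      int p = idx.pos[t] - off;
      if (idx.circular) p = ((p % idx.n) + idx.n) % idx.n;
      else if (p < 0 || p + L > idx.n) continue;
      cand.push_back(p);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (int p : cand) {
    int mm = count_mm(idx, q, p, maxmm);
    if (mm <= maxmm) out.push_back({p, minus, mm});
  }
}

static void map_one(const SeedIndex& idx, const std::string& q,
                    double min_identity, std::vector<Hit>& hits) {
  int L = (int)q.size();
  int maxmm = (int)std::floor(L * (1.0 - min_identity) + 1e-9);
  scan_orientation(idx, q, maxmm, false, hits);
  std::string rc = revcomp_str(q);
  std::vector<Hit> mhits;
  scan_orientation(idx, rc, maxmm, true, mhits);
  hits.insert(hits.end(), mhits.begin(), mhits.end());
  std::stable_sort(hits.begin(), hits.end(),
                   [](const Hit& a, const Hit& b) { return a.mm < b.mm; });
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector queries, std::string genome_seq,
                        double min_identity, bool circular) {
  SeedIndex idx;
  build_seed_index(genome_seq, circular, 64, idx);
  std::vector<int> qidx, refstart, mmv;
  std::vector<int> strandv;
  for (int i = 0; i < queries.size(); ++i) {
    std::string q = as<std::string>(queries[i]);
    std::vector<Hit> hits;
    map_one(idx, q, min_identity, hits);
    int L = (int)q.size();
    for (const Hit& h : hits) {
      qidx.push_back(i + 1);
      // ref_start = forward coord of the query's 5'-most aligned base
      int rs = h.minus ? h.fwd_left + L - 1 : h.fwd_left;
      if (circular) rs = rs % idx.n;
      refstart.push_back(rs + 1); // 1-based
      strandv.push_back(h.minus ? -1 : 1);
      mmv.push_back(h.mm);
    }
  }
  return DataFrame::create(_["query"] = qidx, _["ref_start"] = refstart,
                           _["strand"] = strandv, _["mismatches"] = mmv);
}

// concordance: opposite strands, forward-reverse orientation, fragment span
// in (0, max_insert] measured 5'->3' from the read-1 start (circular-aware)
static inline bool concordant(const SeedIndex& idx, const Hit& h1, int L1,
                              const Hit& h2, int L2, int max_insert,
                              int& span) {
  if (h1.minus == h2.minus) return false;
  long long d;
  if (!h1.minus) d = (long long)(h2.fwd_left + L2 - 1) - h1.fwd_left;
  else          d = (long long)(h1.fwd_left + L1 - 1) - h2.fwd_left;
  if (idx.circular) d = ((d % idx.n) + idx.n) % idx.n;
  else if (d < 0) return false;
  span = (int)d + 1;
  return span >= std::max(L1, L2) && span <= max_insert;
}

// [[Rcpp::export(name = ".cpp_map_pairs")]]
DataFrame cpp_map_pairs(CharacterVector q1, CharacterVector q2,
                        std::string genome_seq, double min_identity,
                        int max_insert, bool circular) {
  SeedIndex idx;
  build_seed_index(genome_seq, circular, 64, idx);
  int n = q1.size();
  IntegerVector r1_start(n, NA_INTEGER), r1_mm(n, NA_INTEGER),
      r2_start(n, NA_INTEGER), r2_mm(n, NA_INTEGER), spanv(n, NA_INTEGER);
  CharacterVector status(n), r1_strand(n, NA_STRING), r2_strand(n, NA_STRING);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(q1[i]);
    std::string s2 = as<std::string>(q2[i]);
    std::vector<Hit> h1, h2;
    map_one(idx, s1, min_identity, h1);
    if (h1.empty()) { status[i] = "unmapped"; continue; }
    map_one(idx, s2, min_identity, h2);
    int L1 = (int)s1.size(), L2 = (int)s2.size();
    // best concordant pairing by summed identity == fewest summed mismatches
    int best = INT32_MAX, nbest = 0, bi = -1, bj = -1, bspan = 0;
    for (size_t a = 0; a < h1.size(); ++a) {
      for (size_t b = 0; b < h2.size(); ++b) {
        int span;
        if (!concordant(idx, h1[a], L1, h2[b], L2, max_insert, span)) continue;
        int mmsum = h1[a].mm + h2[b].mm;
        if (mmsum < best) { best = mmsum; nbest = 1; bi = (int)a; bj = (int)b; bspan = span; }
        else if (mmsum == best) ++nbest;
      }
    }
    if (bi < 0) { status[i] = "discordant"; continue; }
    if (nbest > 1) { status[i] = "ambiguous"; continue; }
    status[i] = "unique";
    const Hit& H1 = h1[bi]; const Hit& H2 = h2[bj];
    r1_start[i] = (H1.minus ? H1.fwd_left + L1 - 1 : H1.fwd_left) % (circular ? idx.n : INT32_MAX) + 1;
    r2_start[i] = (H2.minus ? H2.fwd_left + L2 - 1 : H2.fwd_left) % (circular ? idx.n : INT32_MAX) + 1;
    r1_strand[i] = H1.minus ? "-" : "+";
    r2_strand[i] = H2.minus ? "-" : "+";
    r1_mm[i] = H1.mm; r2_mm[i] = H2.mm;
    spanv[i] = bspan;
  }
  return DataFrame::create(
      _["status"] = status, _["r1_ref_start"] = r1_start,
      _["r1_strand"] = r1_strand, _["r1_mismatches"] = r1_mm,
      _["r2_ref_start"] = r2_start, _["r2_strand"] = r2_strand,
      _["r2_mismatches"] = r2_mm, _["span"] = spanv);
}
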