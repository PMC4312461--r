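#include "pv_common.h"
#include <algorithm>
using namespace Rcpp;

// Exact k-mer position index over the reference: packed (kmer << 25 | pos)
// keys in a sorted vector, queried by binary search. Positions of k-mers
// containing ambiguous bases are excluded.
struct PvIndex {
  int k;
  std::string ref;
  std::vector<uint64_t> table;
};

static const int PV_POS_BITS = 25; // references up to 2^25 (~33 Mbp)

// [[Rcpp::export]]
SEXP cpp_build_index(std::string ref, int k) {
  if (k < 4) stop("k must be >= 4");
  if (k > 16) stop("k must be <= 16");
  if ((double)ref.size() >= (double)(1L << PV_POS_BITS))
    stop("reference too long for the index");
  PvIndex *idx = new PvIndex();
  idx->k = k;
  idx->ref = ref;
  const int L = (int)ref.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t kmer = 0;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int b = pv_encode(ref[i]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++valid >= k)
      idx->table.push_back((kmer << PV_POS_BITS) | (uint64_t)(i - k + 1));
  }
  std::sort(idx->table.begin(), idx->table.end());
  XPtr<PvIndex> p(idx, true);
  p.attr("class") = "pv_index";
  return p;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<PvIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length != k");
  uint64_t key = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = pv_encode(kmer[i]);
    if (b < 0) return IntegerVector(0);
    key = (key << 2) | (uint64_t)b;
  }
  uint64_t lo = key << PV_POS_BITS, hi = (key + 1) << PV_POS_BITS;
  std::vector<uint64_t>::const_iterator a =
      std::lower_bound(idx->table.begin(), idx->table.end(), lo);
  std::vector<uint64_t>::const_iterator b =
      std::lower_bound(idx->table.begin(), idx->table.end(), hi);
  IntegerVector out(b - a);
  for (int i = 0; a + i != b; ++i)
    out[i] = (int)((a[i]) & ((1ULL << PV_POS_BITS) - 1));
  return out;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) {
  XPtr<PvIndex> idx(xp);
  return idx->k;
}

// ---- banded semi-global alignment ------------------------------------------

// Alignment of the full query against a reference window starting at ws
// (query position i aligns near window column i + band); leading and trailing
// reference overhang is free. Returns the minimum edit distance; fills
// traceback and reports the alignment's reference start and CIGAR when tb is
// true. Window positions outside [0, L) never match (sentinel).
struct PvAln {
  int score;
  int ref_start;
  std::string cigar;
};

static int pv_banded(const std::string &ref, const std::string &q, int ws,
                     int band, int cap, bool tb, PvAln *out) {
  const int m = (int)q.size();
  const int W = 2 * band + 1; // allowed j - i offsets 0 .. 2*band
  const int L = (int)ref.size();
  const int BIG = 1 << 28;
  std::vector<int> prev(W + 2, BIG), cur(W + 2, BIG);
  // ptr codes: 0 diag, 1 up (I), 2 left (D); row-major (m+1) x W
  std::vector<unsigned char> ptr(tb ? (size_t)(m + 1) * W : 0);
  for (int c = 0; c <= 2 * band; ++c) prev[c + 1] = 0; // row 0: free start
  for (int i = 1; i <= m; ++i) {
    int rowmin = BIG;
    for (int c = 0; c <= 2 * band; ++c) {
      const int j = i + c; // window column (1-based)
      const int g = ws + j - 1; // global ref position of column j
      const char rb = (g >= 0 && g < L) ? ref[g] : '\0';
      const int sub = (rb != '\0' && rb == q[i - 1]) ? 0 : 1;
      int best = prev[c + 1] + sub; // diag: (i-1, j-1) has same offset c
      int code = 0;
      if (prev[c + 2] + 1 < best) { best = prev[c + 2] + 1; code = 1; } // up
      if (cur[c] + 1 < best) { best = cur[c] + 1; code = 2; } // left
      cur[c + 1] = best;
      if (tb) ptr[(size_t)i * W + c] = (unsigned char)code;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > cap) return BIG; // early abandon
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), BIG);
  }
  int bestc = 0, best = BIG;
  for (int c = 0; c <= 2 * band; ++c)
    if (prev[c + 1] < best) { best = prev[c + 1]; bestc = c; }
  if (!tb || best > cap) return best;
  // among equal-score end columns prefer one whose final op is a diagonal,
  // so a terminal mismatch is never re-expressed as a terminal indel
  for (int c = 0; c <= 2 * band; ++c)
    if (prev[c + 1] == best && ptr[(size_t)m * W + c] == 0) { bestc = c; break; }
  // traceback
  std::string ops;
  int i = m, c = bestc;
  while (i > 0) {
    unsigned char code = ptr[(size_t)i * W + c];
    if (code == 0) { ops.push_back('M'); --i; }
    else if (code == 1) { ops.push_back('I'); --i; ++c; }
    else { ops.push_back('D'); --c; }
  }
  std::reverse(ops.begin(), ops.end());
  out->score = best;
  out->ref_start = ws + c; // leading free columns consumed
  out->cigar = ops; // expanded ops; compressed by caller after left-alignment
  return best;
}

// Shift I/D runs leftwards while the flanking sequence permits, so indel
// placement is canonical (matters for the +-3 bp indel matching window).
static void pv_left_align(std::string &ops, int ref_start,
                          const std::string &ref, const std::string &q) {
  bool moved = true;
  while (moved) {
    moved = false;
    // current coordinates walked fresh each pass; indels are few and short
    size_t n = ops.size();
    int rp = ref_start, qp = 0;
    for (size_t i = 0; i < n; ++i) {
      char op = ops[i];
      if (op == 'M') { ++rp; ++qp; continue; }
      // find run extent
      size_t j = i;
      while (j + 1 < n && ops[j + 1] == op) ++j;
      const int len = (int)(j - i + 1);
      if (i > 0 && ops[i - 1] == 'M') {
        if (op == 'D') {
          // deleted ref run occupies rp .. rp+len-1; can shift if the base
          // before the run equals the last base of the run
          if (rp > 0 && rp + len - 1 < (int)ref.size() &&
              ref[rp - 1] == ref[rp + len - 1]) {
            ops[i - 1] = 'D'; ops[j] = 'M';
            moved = true;
          }
        } else { // 'I'
          if (qp > 0 && qp + len - 1 < (int)q.size() &&
              q[qp - 1] == q[qp + len - 1]) {
            ops[i - 1] = 'I'; ops[j] = 'M';
            moved = true;
          }
        }
      }
      if (op == 'D') rp += len; else qp += len;
      i = j;
      if (moved) break;
    }
  }
}

static std::string pv_compress_cigar(const std::string &ops) {
  std::string out;
  size_t i = 0;
  char buf[16];
  while (i < ops.size()) {
    size_t j = i;
    while (j + 1 < ops.size() && ops[j + 1] == ops[i]) ++j;
    snprintf(buf, sizeof(buf), "%d%c", (int)(j - i + 1), ops[i]);
    out += buf;
    i = j + 1;
  }
  return out;
}

// ---- read mapping ----------------------------------------------------------

// Candidate loci are found by looking up read k-mers (every seed_step
// positions, both strands) and clustering hit diagonals; each cluster is
// scored by banded alignment. A read is reported mapped only when a single
// cluster attains the best score within the edit-distance cap (unique-best
// policy); ties across clusters or strands leave the read unmapped.
// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector seqs, double max_mismatch_frac,
                   int band, int seed_step) {
  XPtr<PvIndex> idx(xp);
  const int k = idx->k;
  const std::string &ref = idx->ref;
  const std::vector<uint64_t> &table = idx->table;
  const int n = seqs.size();
  if (seed_step < 1) stop("seed_step must be >= 1");
  LogicalVector mapped(n);
  IntegerVector pos(n, NA_INTEGER), nm(n, NA_INTEGER), mapq(n, NA_INTEGER),
      ref_span(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING), cigar(n, NA_STRING);

  std::vector<long long> diags; // (strand << 40) | (diag + 2^30), sortable
  const long long OFF = 1LL << 30;

  for (int r = 0; r < n; ++r) {
    const std::string fwd = as<std::string>(seqs[r]);
    const int m = (int)fwd.size();
    if (m < k) continue;
    const int cap = (int)std::ceil(max_mismatch_frac * m - 1e-9);
    const std::string rev = pv_revcomp(fwd);
    diags.clear();
    for (int st = 0; st < 2; ++st) {
      const std::string &q = (st == 0) ? fwd : rev;
      uint64_t kmer = 0;
      const uint64_t mask = (1ULL << (2 * k)) - 1;
      int valid = 0;
      for (int i = 0; i < m; ++i) {
        int b = pv_encode(q[i]);
        if (b < 0) { valid = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++valid < k) continue;
        const int sp = i - k + 1; // seed start in query
        if (sp % seed_step != 0 && i != m - 1) continue;
        uint64_t lo = kmer << PV_POS_BITS, hi = (kmer + 1) << PV_POS_BITS;
        std::vector<uint64_t>::const_iterator a =
            std::lower_bound(table.begin(), table.end(), lo);
        for (; a != table.end() && *a < hi; ++a) {
          const int p = (int)(*a & ((1ULL << PV_POS_BITS) - 1));
          diags.push_back(((long long)st << 40) | (long long)(p - sp + OFF));
        }
      }
    }
    if (diags.empty()) continue;
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());

    // cluster diagonals (same strand, gap <= band) into candidate loci
    struct Cand { int st; int anchor; };
    std::vector<Cand> cands;
    for (size_t i = 0; i < diags.size();) {
      const int st = (int)(diags[i] >> 40);
      const long long d0 = (diags[i] & ((1LL << 40) - 1)) - OFF;
      size_t j = i;
      long long dprev = d0;
      while (j + 1 < diags.size() && (int)(diags[j + 1] >> 40) == st) {
        long long dn = (diags[j + 1] & ((1LL << 40) - 1)) - OFF;
        if (dn - dprev > band) break;
        dprev = dn;
        ++j;
      }
      Cand c1; c1.st = st; c1.anchor = (int)((d0 + dprev) / 2);
      cands.push_back(c1);
      i = j + 1;
    }

    int best = 1 << 28, second = 1 << 28, besti = -1;
    int nbest = 0;
    if (cands.size() > 1) { // score candidates; skip when the locus is unique
      for (size_t ci = 0; ci < cands.size(); ++ci) {
        const std::string &q = (cands[ci].st == 0) ? fwd : rev;
        int s = pv_banded(ref, q, cands[ci].anchor - band, band, cap, false,
                          NULL);
        if (s < best) {
          second = best; best = s; besti = (int)ci; nbest = 1;
        } else if (s == best) {
          ++nbest;
          if (s < second) second = s;
        } else if (s < second) {
          second = s;
        }
      }
      if (besti < 0 || best > cap || nbest > 1) continue; // unmapped
    } else {
      besti = 0;
    }
    const std::string &q = (cands[besti].st == 0) ? fwd : rev;
    PvAln aln;
    int s = pv_banded(ref, q, cands[besti].anchor - band, band, cap, true,
                      &aln);
    if (s > cap) continue; // single candidate over the edit-distance cap
    best = s;
    std::string ops = aln.cigar;
    pv_left_align(ops, aln.ref_start, ref, q);
    // a deletion shifted to the alignment boundary is just a different start
    while (!ops.empty() && ops[ops.size() - 1] == 'D') ops.erase(ops.size() - 1);
    while (!ops.empty() && ops[0] == 'D') { ops.erase(0, 1); ++aln.ref_start; }
    mapped[r] = true;
    pos[r] = aln.ref_start; // 0-based
    {
      int span = 0;
      for (size_t oi = 0; oi < ops.size(); ++oi)
        if (ops[oi] != 'I') ++span;
      ref_span[r] = span;
    }
    nm[r] = aln.score;
    strand[r] = (cands[besti].st == 0) ? "+" : "-";
    cigar[r] = pv_compress_cigar(ops);
    mapq[r] = (second > cap) ? 37 : std::min(37, 10 * (second - best));
  }
  return List::create(_["mapped"] = mapped, _["pos"] = pos, _["nm"] = nm,
                      _["mapq"] = mapq, _["strand"] = strand,
                      _["cigar"] = cigar, _["ref_span"] = ref_span);
}
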