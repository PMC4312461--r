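#include "pv_common.h"
using namespace Rcpp;

// Maximum per-end offset tracked in the aggregated damage ledger. The damage
// model itself never reaches past the position where p0 * decay^i < cutoff
// (13 for the strongest preset), so 32 is safely beyond any configuration
// used in practice.
static const int PV_LEDGER_W = 32;

// Number of read positions (per end) with misincorporation probability >=
// cutoff. Mirrors eligible_positions() on the R side.
static int pv_eligible(double p0, double decay, double cutoff) {
  if (p0 < cutoff) return 0;
  int n = 0;
  double p = p0;
  while (p >= cutoff && n < 10000) { ++n; p *= decay; }
  return n;
}

// Apply terminal deamination to a single read (as sequenced): C->T scanning
// from the 5' end, G->A scanning from the 3' end, probability p0 * decay^i at
// offset i, both tracks applied independently. Opportunities and flips are
// accumulated into the ledger arrays; flipped read offsets are appended to
// `edits` when it is non-null.
static void pv_damage_read(std::string &seq, double p0, double decay,
                           double cutoff, long *opp5, long *flip5, long *opp3,
                           long *flip3, std::vector<int> *edits) {
  const int n5 = pv_eligible(p0, decay, cutoff);
  const int L = (int)seq.size();
  double p = p0;
  for (int i = 0; i < n5 && i < L; ++i, p *= decay) {
    if (seq[i] == 'C') {
      if (i < PV_LEDGER_W) ++opp5[i];
      if (unif_rand() < p) {
        seq[i] = 'T';
        if (i < PV_LEDGER_W) ++flip5[i];
        if (edits) edits->push_back(i);
      }
    }
  }
  p = p0;
  for (int i = 0; i < n5 && i < L; ++i, p *= decay) {
    const int j = L - 1 - i;
    if (seq[j] == 'G') {
      if (i < PV_LEDGER_W) ++opp3[i];
      if (unif_rand() < p) {
        seq[j] = 'A';
        if (i < PV_LEDGER_W) ++flip3[i];
        if (edits) edits->push_back(j);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_apply_damage(CharacterVector seqs, double p0, double decay,
                      double cutoff, bool keep_edits) {
  const int n = seqs.size();
  CharacterVector out(n);
  std::vector<long> opp5(PV_LEDGER_W, 0), flip5(PV_LEDGER_W, 0),
      opp3(PV_LEDGER_W, 0), flip3(PV_LEDGER_W, 0);
  List edits(keep_edits ? n : 0);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::vector<int> ed;
    pv_damage_read(s, p0, decay, cutoff, opp5.data(), flip5.data(),
                   opp3.data(), flip3.data(), keep_edits ? &ed : NULL);
    out[r] = s;
    if (keep_edits) {
      IntegerVector v(ed.begin(), ed.end());
      edits[r] = v + 1; // 1-based read positions for the R side
    }
  }
  return List::create(
      _["seq"] = out, _["edits"] = edits,
      _["opp5"] = IntegerVector(opp5.begin(), opp5.end()),
      _["flip5"] = IntegerVector(flip5.begin(), flip5.end()),
      _["opp3"] = IntegerVector(opp3.begin(), opp3.end()),
      _["flip3"] = IntegerVector(flip3.begin(), flip3.end()));
}

// Fused read-pool generator: draws raw 100 bp fragments uniformly from both
// strands of both chromosomes, trims to a target-length distribution (5' end
// kept), applies fragmentation-biased acceptance based on the genomic
// neighbours of the trimmed footprint, injects uniform sequencing errors, and
// applies terminal deamination. Distributionally identical to composing
// generate_raw_reads() + trim_reads() + accept_fragment() +
// apply_misincorporation(), but never materializes rejected or trimmed-away
// bases.
//
// w5/w3 are acceptance weights in A,C,G,T order for the genomic base
// immediately 5' of the fragment start / 3' of the fragment end on the
// read's source strand; a missing neighbour (contig end) has weight 1.
// [[Rcpp::export]]
List cpp_generate_pool(List chroms, double target_bases,
                       IntegerVector len_support, NumericVector len_prob,
                       int raw_len, double err_rate, double p0, double decay,
                       double cutoff, NumericVector w5, NumericVector w3,
                       double base_accept, bool keep_edits, int max_reads) {
  const int nchr = chroms.size();
  std::vector<std::string> chr(nchr);
  for (int i = 0; i < nchr; ++i) chr[i] = as<std::string>(chroms[i]);
  for (int i = 0; i < nchr; ++i)
    if ((int)chr[i].size() < raw_len)
      stop("chromosome shorter than the raw read length");
  const int nlen = len_support.size();
  std::vector<double> cum(nlen);
  double tot = 0;
  for (int i = 0; i < nlen; ++i) { tot += len_prob[i]; cum[i] = tot; }
  for (int i = 0; i < nlen; ++i) cum[i] /= tot;
  double mx5 = 1e-12, mx3 = 1e-12;
  for (int i = 0; i < 4; ++i) {
    if (w5[i] > mx5) mx5 = w5[i];
    if (w3[i] > mx3) mx3 = w3[i];
  }

  std::vector<int> v_chrom, v_start, v_len, v_nerr;
  std::vector<char> v_minus;
  std::vector<std::string> v_seq;
  List edits(0);
  std::vector<std::vector<int> > ed_store;
  std::vector<long> opp5(PV_LEDGER_W, 0), flip5(PV_LEDGER_W, 0),
      opp3(PV_LEDGER_W, 0), flip3(PV_LEDGER_W, 0);

  double acc_bases = 0;
  long tried = 0;
  const double log1me = (err_rate > 0 && err_rate < 1) ? std::log1p(-err_rate) : 0.0;

  // max_reads > 0 means "generate exactly this many accepted reads";
  // otherwise accepted bases accumulate until target_bases is reached.
  while (max_reads > 0 ? (int)v_seq.size() < max_reads
                       : acc_bases < target_bases) {
    ++tried;
    if (tried > 500000000L) stop("fragment rejection loop did not terminate");
    const int ci = (nchr == 1) ? 0 : (unif_rand() < 0.5 ? 0 : 1);
    const std::string &C = chr[ci];
    const int Lc = (int)C.size();
    int s0 = (int)(unif_rand() * (Lc - raw_len + 1));
    if (s0 > Lc - raw_len) s0 = Lc - raw_len;
    // trimmed length
    double u = unif_rand();
    int Lt = len_support[nlen - 1];
    for (int i = 0; i < nlen; ++i)
      if (u <= cum[i]) { Lt = len_support[i]; break; }
    const bool minus = unif_rand() < 0.5;
    const int fs = minus ? s0 + raw_len - Lt : s0;
    const int fe = fs + Lt;
    // fragmentation-bias acceptance from genomic neighbours on source strand
    double wa = 1.0, wb = 1.0;
    if (!minus) {
      if (fs > 0) { int b = pv_encode(C[fs - 1]); wa = b >= 0 ? w5[b] : 1.0; }
      if (fe < Lc) { int b = pv_encode(C[fe]); wb = b >= 0 ? w3[b] : 1.0; }
    } else {
      if (fe < Lc) { int b = pv_encode(pv_comp(C[fe])); wa = b >= 0 ? w5[b] : 1.0; }
      if (fs > 0) { int b = pv_encode(pv_comp(C[fs - 1])); wb = b >= 0 ? w3[b] : 1.0; }
    }
    const double pacc = base_accept * (wa * wb) / (mx5 * mx3);
    if (unif_rand() >= pacc) continue;

    std::string s = C.substr(fs, Lt);
    if (minus) s = pv_revcomp(s);
    // sequencing errors: geometric skipping between error positions
    int nerr = 0;
    if (err_rate > 0) {
      int i = -1;
      while (true) {
        double uu = unif_rand();
        int gap = (err_rate >= 1) ? 1 : (int)std::floor(std::log(uu) / log1me) + 1;
        i += gap;
        if (i >= Lt) break;
        int b = pv_encode(s[i]);
        if (b >= 0) {
          int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
          s[i] = pv_decode(nb);
          ++nerr;
        }
      }
    }
    std::vector<int> ed;
    pv_damage_read(s, p0, decay, cutoff, opp5.data(), flip5.data(),
                   opp3.data(), flip3.data(), keep_edits ? &ed : NULL);
    v_chrom.push_back(ci + 1);
    v_start.push_back(fs);
    v_len.push_back(Lt);
    v_minus.push_back(minus ? 1 : 0);
    v_nerr.push_back(nerr);
    v_seq.push_back(s);
    if (keep_edits) ed_store.push_back(ed);
    acc_bases += Lt;
  }

  const int n = (int)v_seq.size();
  CharacterVector seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = v_seq[i];
  LogicalVector minus(n);
  for (int i = 0; i < n; ++i) minus[i] = v_minus[i] != 0;
  if (keep_edits) {
    edits = List(n);
    for (int i = 0; i < n; ++i) {
      IntegerVector v(ed_store[i].begin(), ed_store[i].end());
      edits[i] = v + 1;
    }
  }
  return List::create(
      _["chrom"] = IntegerVector(v_chrom.begin(), v_chrom.end()),
      _["start"] = IntegerVector(v_start.begin(), v_start.end()),
      _["len"] = IntegerVector(v_len.begin(), v_len.end()),
      _["minus"] = minus,
      _["n_err"] = IntegerVector(v_nerr.begin(), v_nerr.end()),
      _["seq"] = seqs, _["edits"] = edits, _["tried"] = (double)tried,
      _["opp5"] = IntegerVector(opp5.begin(), opp5.end()),
      _["flip5"] = IntegerVector(flip5.begin(), flip5.end()),
      _["opp3"] = IntegerVector(opp3.begin(), opp3.end()),
      _["flip3"] = IntegerVector(flip3.begin(), flip3.end()));
}

// Uniform per-base substitution errors for standalone use in tests.
// [[Rcpp::export]]
List cpp_add_seq_errors(CharacterVector seqs, double err_rate) {
  const int n = seqs.size();
  CharacterVector out(n);
  List pos(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    std::vector<int> p;
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() < err_rate) {
        int b = pv_encode(s[i]);
        if (b >= 0) {
          s[i] = pv_decode((b + 1 + (int)(unif_rand() * 3)) & 3);
          p.push_back((int)i + 1);
        }
      }
    }
    out[r] = s;
    IntegerVector v(p.begin(), p.end());
    pos[r] = v;
  }
  return List::create(_["seq"] = out, _["err_pos"] = pos);
}
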