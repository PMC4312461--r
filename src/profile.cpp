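#include "pv_common.h"
using namespace Rcpp;

// Observed misincorporation tallies from mapped reads, mapDamage-style:
// per read offset from the 5' end, reference C -> read T opportunities and
// events; per offset from the 3' end, reference G -> read A. Only CIGAR M
// columns count as opportunities. Reverse-strand reads are complemented so
// offsets and bases are in sequenced-read orientation.
// [[Rcpp::export]]
List cpp_misincorporation_profile(std::string ref, IntegerVector pos,
                                  CharacterVector strand,
                                  CharacterVector cigar, CharacterVector seq,
                                  int max_offset) {
  const int L = (int)ref.size();
  const int n = pos.size();
  IntegerVector opp5(max_offset), ct5(max_offset), opp3(max_offset),
      ga3(max_offset);
  for (int r = 0; r < n; ++r) {
    std::string q = as<std::string>(seq[r]);
    const bool minus = (as<std::string>(strand[r]) == "-");
    if (minus) q = pv_revcomp(q);
    const int m = (int)q.size();
    const std::string cg = as<std::string>(cigar[r]);
    int rp = pos[r], qp = 0;
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) len = len * 10 + (cg[ci++] - '0');
      const char op = cg[ci++];
      if (op == 'M') {
        for (int i = 0; i < len; ++i, ++rp, ++qp) {
          if (rp < 0 || rp >= L) continue;
          // orientation of template and observed base as sequenced
          const char tmpl = minus ? pv_comp(ref[rp]) : ref[rp];
          const char obs = minus ? pv_comp(q[qp]) : q[qp];
          const int off5 = minus ? (m - 1 - qp) : qp;
          const int off3 = m - 1 - off5;
          if (tmpl == 'C' && off5 < max_offset) {
            ++opp5[off5];
            if (obs == 'T') ++ct5[off5];
          }
          if (tmpl == 'G' && off3 < max_offset) {
            ++opp3[off3];
            if (obs == 'A') ++ga3[off3];
          }
        }
      } else if (op == 'I') {
        qp += len;
      } else if (op == 'D') {
        rp += len;
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }
  return List::create(_["opp5"] = opp5, _["ct5"] = ct5, _["opp3"] = opp3,
                      _["ga3"] = ga3);
}
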