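#include "pv_common.h"
#include <map>
#include <cmath>
using namespace Rcpp;

// Diploid pileup genotyper over mapped reads. Per column, genotype
// likelihoods over {hom-ref, het, hom-alt} from per-base error rates, a
// samtools-style prior on non-reference genotypes (theta for het, theta/2
// for hom-alt), and QUAL = -10 log10 posterior(hom-ref). Indels are called
// from inserted/deleted observations recorded in the CIGARs with the same
// machinery on support counts. Per-call strand (DP4) and distance-to-read-end
// summaries are emitted so bias filters can be applied downstream.
// [[Rcpp::export]]
List cpp_pileup_call(std::string ref, IntegerVector pos,
                     CharacterVector strand, CharacterVector cigar,
                     CharacterVector seq, double eps, double eps_indel,
                     double theta_snp, double theta_indel) {
  const int L = (int)ref.size();
  const int n = pos.size();
  // per-column accumulators
  std::vector<uint16_t> cntf(4L * L, 0), cntr(4L * L, 0);
  std::vector<float> tsum(4L * L, 0.0f), tsum2(4L * L, 0.0f);
  std::vector<int32_t> cover(L, 0);
  typedef std::map<std::string, int> AlleleMap;
  std::map<int, AlleleMap> indels;

  int last = -1;
  for (int r = 0; r < n; ++r) {
    if (pos[r] < last) stop("reads must be sorted by reference start");
    last = pos[r];
    std::string q = as<std::string>(seq[r]);
    const bool minus = (as<std::string>(strand[r]) == "-");
    if (minus) q = pv_revcomp(q); // aligned orientation
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
          const int b = pv_encode(q[qp]);
          if (b < 0) continue;
          const int td = std::min(qp, m - 1 - qp);
          const size_t ix = (size_t)b * L + rp;
          if (minus) { if (cntr[ix] < 65535) ++cntr[ix]; }
          else { if (cntf[ix] < 65535) ++cntf[ix]; }
          tsum[ix] += (float)td;
          tsum2[ix] += (float)(td * td);
          ++cover[rp];
        }
      } else if (op == 'I') {
        const int anchor = rp - 1;
        if (anchor >= 0 && anchor < L && qp + len <= m)
          ++indels[anchor][std::string("+") + q.substr(qp, len)];
        qp += len;
      } else if (op == 'D') {
        const int anchor = rp - 1;
        if (anchor >= 0 && anchor < L) {
          char buf[16];
          snprintf(buf, sizeof(buf), "-%d", len);
          ++indels[anchor][std::string(buf)];
        }
        for (int i = 0; i < len; ++i, ++rp)
          if (rp >= 0 && rp < L) ++cover[rp];
      } else {
        stop("unsupported CIGAR op");
      }
    }
  }

  const double le = std::log(eps / 3.0), l1 = std::log(1.0 - eps);
  const double lh = std::log(0.5 * (1.0 - eps) + 0.5 * eps / 3.0);
  const double lpRR = std::log(1.0 - 1.5 * theta_snp);
  const double lpRA = std::log(theta_snp);
  const double lpAA = std::log(theta_snp / 2.0);

  std::vector<int> o_pos, o_gt, o_depth, o_dp4a, o_dp4b, o_dp4c, o_dp4d,
      o_nref, o_nalt;
  std::vector<std::string> o_type, o_ref, o_alt;
  std::vector<double> o_qual, o_tmr, o_tvr, o_tma, o_tva;

  // SNP scan
  for (int p = 0; p < L; ++p) {
    const int rb = pv_encode(ref[p]);
    if (rb < 0) continue;
    int cnt[4], ntot = 0;
    for (int b = 0; b < 4; ++b) {
      cnt[b] = cntf[(size_t)b * L + p] + cntr[(size_t)b * L + p];
      ntot += cnt[b];
    }
    if (ntot == 0) continue;
    int alt = -1, am = 0;
    for (int b = 0; b < 4; ++b)
      if (b != rb && cnt[b] > am) { am = cnt[b]; alt = b; }
    if (alt < 0 || am == 0) continue;
    const double lRR = cnt[rb] * l1 + (ntot - cnt[rb]) * le + lpRR;
    const double lAA = cnt[alt] * l1 + (ntot - cnt[alt]) * le + lpAA;
    const double lRA =
        (cnt[rb] + cnt[alt]) * lh + (ntot - cnt[rb] - cnt[alt]) * le + lpRA;
    double mx = std::max(lRR, std::max(lAA, lRA));
    if (lRR >= lRA && lRR >= lAA) continue; // hom-ref is ML genotype
    const double den =
        std::exp(lRR - mx) + std::exp(lRA - mx) + std::exp(lAA - mx);
    double postRR = std::exp(lRR - mx) / den;
    if (postRR < 1e-30) postRR = 1e-30;
    const double qual = -10.0 * std::log10(postRR);
    const size_t ixr = (size_t)rb * L + p, ixa = (size_t)alt * L + p;
    const int nr = cnt[rb], na = cnt[alt];
    const double tmr = nr > 0 ? tsum[ixr] / nr : NA_REAL;
    const double tma = na > 0 ? tsum[ixa] / na : NA_REAL;
    const double tvr =
        nr > 1 ? (tsum2[ixr] - (double)tsum[ixr] * tsum[ixr] / nr) / (nr - 1)
               : NA_REAL;
    const double tva =
        na > 1 ? (tsum2[ixa] - (double)tsum[ixa] * tsum[ixa] / na) / (na - 1)
               : NA_REAL;
    o_pos.push_back(p);
    o_type.push_back("snp");
    o_ref.push_back(std::string(1, ref[p]));
    o_alt.push_back(std::string(1, pv_decode(alt)));
    o_gt.push_back(lAA > lRA ? 2 : 1);
    o_qual.push_back(qual);
    o_depth.push_back(cover[p]);
    o_dp4a.push_back(cntf[ixr]);
    o_dp4b.push_back(cntr[ixr]);
    o_dp4c.push_back(cntf[ixa]);
    o_dp4d.push_back(cntr[ixa]);
    o_nref.push_back(nr);
    o_nalt.push_back(na);
    o_tmr.push_back(tmr);
    o_tvr.push_back(tvr);
    o_tma.push_back(tma);
    o_tva.push_back(tva);
  }

  // indel scan
  const double lei = std::log(eps_indel), l1i = std::log(1.0 - eps_indel);
  const double lhi = std::log(0.5);
  const double lpRRi = std::log(1.0 - 1.5 * theta_indel);
  const double lpRAi = std::log(theta_indel);
  const double lpAAi = std::log(theta_indel / 2.0);
  for (std::map<int, AlleleMap>::const_iterator it = indels.begin();
       it != indels.end(); ++it) {
    const int p = it->first;
    std::string allele;
    int sup = 0;
    for (AlleleMap::const_iterator a = it->second.begin();
         a != it->second.end(); ++a)
      if (a->second > sup) { sup = a->second; allele = a->first; }
    if (sup == 0) continue;
    const int depth = cover[p];
    const int ns = std::max(0, depth - sup);
    const double lRR = sup * lei + ns * l1i + lpRRi;
    const double lAA = ns * lei + sup * l1i + lpAAi;
    const double lRA = (sup + ns) * lhi + lpRAi;
    if (lRR >= lRA && lRR >= lAA) continue;
    double mx = std::max(lRR, std::max(lAA, lRA));
    const double den =
        std::exp(lRR - mx) + std::exp(lRA - mx) + std::exp(lAA - mx);
    double postRR = std::exp(lRR - mx) / den;
    if (postRR < 1e-30) postRR = 1e-30;
    std::string rstr, astr;
    if (allele[0] == '+') {
      rstr = std::string(1, ref[p]);
      astr = rstr + allele.substr(1);
      o_type.push_back("insertion");
    } else {
      int dl = 0; // parse "-<len>" without strtol (keeps glibc deps minimal)
      for (size_t di = 1; di < allele.size(); ++di)
        dl = dl * 10 + (allele[di] - '0');
      if (p + dl >= L) continue;
      rstr = ref.substr(p, dl + 1);
      astr = std::string(1, ref[p]);
      o_type.push_back("deletion");
    }
    o_pos.push_back(p);
    o_ref.push_back(rstr);
    o_alt.push_back(astr);
    o_gt.push_back(lAA > lRA ? 2 : 1);
    o_qual.push_back(-10.0 * std::log10(postRR));
    o_depth.push_back(depth);
    o_dp4a.push_back(NA_INTEGER);
    o_dp4b.push_back(NA_INTEGER);
    o_dp4c.push_back(NA_INTEGER);
    o_dp4d.push_back(NA_INTEGER);
    o_nref.push_back(ns);
    o_nalt.push_back(sup);
    o_tmr.push_back(NA_REAL);
    o_tvr.push_back(NA_REAL);
    o_tma.push_back(NA_REAL);
    o_tva.push_back(NA_REAL);
  }

  return List::create(
      _["pos"] = wrap(o_pos), _["type"] = wrap(o_type),
      _["ref"] = wrap(o_ref), _["alt"] = wrap(o_alt), _["gt"] = wrap(o_gt),
      _["qual"] = wrap(o_qual), _["depth"] = wrap(o_depth),
      _["ref_fwd"] = wrap(o_dp4a), _["ref_rev"] = wrap(o_dp4b),
      _["alt_fwd"] = wrap(o_dp4c), _["alt_rev"] = wrap(o_dp4d),
      _["n_ref"] = wrap(o_nref), _["n_alt"] = wrap(o_nalt),
      _["tail_mean_ref"] = wrap(o_tmr), _["tail_var_ref"] = wrap(o_tvr),
      _["tail_mean_alt"] = wrap(o_tma), _["tail_var_alt"] = wrap(o_tva));
}
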