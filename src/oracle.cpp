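#include "pv_common.h"
#include <algorithm>
using namespace Rcpp;

// Exhaustive semi-global aligner used as an independent check on the
// seed-and-extend mapper: full unbanded edit-distance DP of each read
// against the whole reference (both strands), no seeding, no pruning.
// A read is "mapped" when the best edit distance is within the cap and all
// best-scoring alignments start within `band` of one another.
// [[Rcpp::export]]
List cpp_exhaustive_map(std::string ref, CharacterVector seqs,
                        double max_mismatch_frac, int band) {
  const int L = (int)ref.size();
  const int n = seqs.size();
  LogicalVector mapped(n);
  IntegerVector pos(n, NA_INTEGER), score(n, NA_INTEGER);

  for (int r = 0; r < n; ++r) {
    const std::string fwd = as<std::string>(seqs[r]);
    const int m = (int)fwd.size();
    const int cap = (int)std::ceil(max_mismatch_frac * m - 1e-9);
    int best = 1 << 28;
    std::vector<int> starts; // starts of all best alignments, both strands
    for (int st = 0; st < 2; ++st) {
      const std::string q = (st == 0) ? fwd : pv_revcomp(fwd);
      // ptr[i][j]: 0 diag, 1 ins (query), 2 del (ref); column-rolling DP
      std::vector<int> prev(m + 1), cur(m + 1);
      std::vector<unsigned char> ptr((size_t)(m + 1) * (L + 1));
      for (int i = 0; i <= m; ++i) prev[i] = i; // column 0: leading query ins
      std::vector<int> bestj;
      int stbest = 1 << 28;
      for (int j = 1; j <= L; ++j) {
        cur[0] = 0; // free leading reference
        for (int i = 1; i <= m; ++i) {
          const int sub = (q[i - 1] == ref[j - 1]) ? 0 : 1;
          int v = prev[i - 1] + sub;
          unsigned char code = 0;
          if (cur[i - 1] + 1 < v) { v = cur[i - 1] + 1; code = 1; }
          if (prev[i] + 1 < v) { v = prev[i] + 1; code = 2; }
          cur[i] = v;
          ptr[(size_t)i * (L + 1) + j] = code;
        }
        if (cur[m] < stbest) { stbest = cur[m]; bestj.assign(1, j); }
        else if (cur[m] == stbest) bestj.push_back(j);
        std::swap(prev, cur);
      }
      if (stbest > cap || stbest > best) continue;
      if (stbest < best) { best = stbest; starts.clear(); }
      for (size_t bi = 0; bi < bestj.size(); ++bi) {
        int i = m, j = bestj[bi];
        while (i > 0 && j > 0) {
          unsigned char code = ptr[(size_t)i * (L + 1) + j];
          if (code == 0) { --i; --j; }
          else if (code == 1) { --i; }
          else { --j; }
        }
        starts.push_back(j); // 0-based ref start (or query overhang at 0)
      }
    }
    if (best > cap || starts.empty()) continue;
    std::sort(starts.begin(), starts.end());
    starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
    if (starts.back() - starts.front() > band) continue; // ambiguous
    mapped[r] = true;
    pos[r] = starts.front();
    score[r] = best;
  }
  return List::create(_["mapped"] = mapped, _["pos"] = pos,
                      _["score"] = score);
}
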