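#ifndef PV_COMMON_H
#define PV_COMMON_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>

// Base encoding used throughout: A=0, C=1, G=2, T=3, anything else = -1.
inline int pv_encode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char pv_decode(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return (b >= 0 && b < 4) ? tab[b] : 'N';
}

inline char pv_comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

inline std::string pv_revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = pv_comp(r[i]);
  return r;
}

#endif
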