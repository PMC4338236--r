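// Fast exact-identity grouping of haplotype rows (no missing data),
// used as the first clustering pass and for simulated windows.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".identity_groups")]]
IntegerVector identity_groups(IntegerMatrix m) {
  int n = m.nrow(), S = m.ncol();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    for (int s = 0; s < S; ++s) {
      if (m(a, s) != m(b, s)) return m(a, s) < m(b, s);
    }
    return a < b;
  });
  IntegerVector grp(n);
  int g = 0;
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      bool same = true;
      for (int s = 0; s < S; ++s)
        if (m(ord[i], s) != m(ord[i - 1], s)) { same = false; break; }
      if (!same) ++g;
    }
    grp[ord[i]] = g + 1;
  }
  return grp;
}
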