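// Global alignment with unit costs, used for the long-bubble identity rule.
// Identity = matches / alignment columns, from a minimum-edit-distance
// alignment (tie-break: diagonal > up > left, so mismatches are preferred
// over gaps when costs tie).

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // full DP matrix for traceback; n, m are branch lengths (small)
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(m + 1));
  for (int j = 0; j <= m; ++j) D[0][j] = j;
  for (int i = 1; i <= n; ++i) {
    D[i][0] = i;
    for (int j = 1; j <= m; ++j) {
      int diag = D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int up = D[i - 1][j] + 1;
      int left = D[i][j - 1] + 1;
      D[i][j] = std::min(diag, std::min(up, left));
    }
  }
  int i = n, j = m, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i][j] == D[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && D[i][j] == D[i - 1][j] + 1) {
      --i;
    } else {
      --j;
    }
    ++columns;
  }
  double identity = columns > 0 ? 100.0 * matches / columns : 100.0;
  return List::create(_["matches"] = matches, _["columns"] = columns,
                      _["distance"] = D[n][m], _["identity"] = identity);
}
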