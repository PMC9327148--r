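#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Traceback ties are broken in the fixed order diagonal > up > left
// (up consumes a base of `a`).  N never scores as a match.

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) M(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) M(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double diag = M(i - 1, j - 1) + (is_match ? match : mismatch);
      double up = M(i - 1, j) + gap;
      double left = M(i, j - 1) + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      M(i, j) = best;
    }
  }
  // traceback
  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'N';
      double diag = M(i - 1, j - 1) + (is_match ? match : mismatch);
      if (M(i, j) == diag) {
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && M(i, j) == M(i - 1, j) + gap) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      continue;
    }
    ra.push_back('-');
    rb.push_back(b[j - 1]);
    --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = M(n, m));
}
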