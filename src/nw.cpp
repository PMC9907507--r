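#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment with linear gap penalty.
// Traceback ties are broken diagonal > up > left (up = gap in b,
// i.e. consume a residue of a) so results are reproducible.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);  // 1 = diag, 2 = up, 3 = left

  for (int i = 1; i <= n; ++i) { H(i, 0) = i * gap; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { H(0, j) = j * gap; P(0, j) = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double best = diag;
      int ptr = 1;
      if (up > best)   { best = up;   ptr = 2; }
      if (left > best) { best = left; ptr = 3; }
      H(i, j) = best;
      P(i, j) = ptr;
    }
  }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (ptr == 1)      { ra += a[i - 1]; rb += b[j - 1]; --i; --j; }
    else if (ptr == 2) { ra += a[i - 1]; rb += '-';      --i; }
    else               { ra += '-';      rb += b[j - 1]; --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["score"] = H(n, m));
}
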