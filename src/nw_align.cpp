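#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback tie-break: diagonal > up > left, so exactly one optimal
// alignment is reported. Identity = identical aligned residue pairs /
// alignment length (gap columns included in the denominator).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback codes: 0 diag, 1 up (consume a), 2 left (consume b)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));

  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) { prev[j] = prev[j - 1] + gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = prev[0] + gap;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double d = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double u = prev[j] + gap;
      double l = cur[j - 1] + gap;
      double best = d; unsigned char code = 0;
      if (u > best) { best = u; code = 1; }
      if (l > best) { best = l; code = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = code;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];

  int i = n, j = m, len = 0, ident = 0;
  std::string al_a, al_b;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && code == 0) {
      if (a[i - 1] == b[j - 1]) ++ident;
      al_a.push_back(a[i - 1]); al_b.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 && (code == 1 || j == 0)) {
      al_a.push_back(a[i - 1]); al_b.push_back('-');
      --i;
    } else {
      al_a.push_back('-'); al_b.push_back(b[j - 1]);
      --j;
    }
    ++len;
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());

  return List::create(
    _["score"] = score,
    _["identity"] = len > 0 ? (double)ident / (double)len : 0.0,
    _["matches"] = ident,
    _["length"] = len,
    _["aligned_a"] = al_a,
    _["aligned_b"] = al_b);
}
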