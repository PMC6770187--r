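#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback pointers are stored at fill time with the fixed preference
// diagonal > up (gap in b) > left (gap in a), so the reported alignment is
// deterministic. Scores use a rolling row; pointers keep the full matrix
// (1 byte per cell).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // 0 = diagonal, 1 = up (consume a), 2 = left (consume b)
  std::vector<unsigned char> ptr((size_t)(n + 1) * (m + 1));

  for (int j = 0; j <= m; ++j) {
    prev[j] = j * gap;
    ptr[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    ptr[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int best = diag;
      unsigned char p = 0;
      if (up > best) { best = up; p = 1; }
      if (left > best) { best = left; p = 2; }
      cur[j] = best;
      ptr[(size_t)i * (m + 1) + j] = p;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = ptr[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && p == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (i > 0 && (p == 1 || j == 0)) {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
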