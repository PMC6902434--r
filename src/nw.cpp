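#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh). A gap of length L
// costs gap_open + L * gap_ext (penalties passed as positive numbers).
// End gaps are penalised (true global alignment). Ties are broken
// deterministically: aligned pair > gap in b (consume a) > gap in a.
// N matches nothing, including N.

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // layer 0 = M (pair), 1 = P (gap in b, consumes a), 2 = Q (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG), P((n + 1) * (m + 1), NEG),
      Q((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1),
      tbP((n + 1) * (m + 1), -1), tbQ((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    P[idx(i, 0)] = -(gap_open + gap_ext * i);
    tbP[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Q[idx(0, j)] = -(gap_open + gap_ext * j);
    tbQ[idx(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = subst(a[i - 1], b[j - 1], match, mismatch);
      // M
      double best = M[idx(i - 1, j - 1)];
      signed char tb = 0;
      if (P[idx(i - 1, j - 1)] > best) { best = P[idx(i - 1, j - 1)]; tb = 1; }
      if (Q[idx(i - 1, j - 1)] > best) { best = Q[idx(i - 1, j - 1)]; tb = 2; }
      if (best > NEG) { M[idx(i, j)] = best + s; tbM[idx(i, j)] = tb; }
      // P: gap in b, consume a[i-1]
      best = NEG; tb = -1;
      if (M[idx(i - 1, j)] > NEG &&
          M[idx(i - 1, j)] - gap_open - gap_ext > best) {
        best = M[idx(i - 1, j)] - gap_open - gap_ext; tb = 0;
      }
      if (P[idx(i - 1, j)] > NEG && P[idx(i - 1, j)] - gap_ext > best) {
        best = P[idx(i - 1, j)] - gap_ext; tb = 1;
      }
      if (Q[idx(i - 1, j)] > NEG &&
          Q[idx(i - 1, j)] - gap_open - gap_ext > best) {
        best = Q[idx(i - 1, j)] - gap_open - gap_ext; tb = 2;
      }
      if (tb >= 0) { P[idx(i, j)] = best; tbP[idx(i, j)] = tb; }
      // Q: gap in a, consume b[j-1]
      best = NEG; tb = -1;
      if (M[idx(i, j - 1)] > NEG &&
          M[idx(i, j - 1)] - gap_open - gap_ext > best) {
        best = M[idx(i, j - 1)] - gap_open - gap_ext; tb = 0;
      }
      if (P[idx(i, j - 1)] > NEG &&
          P[idx(i, j - 1)] - gap_open - gap_ext > best) {
        best = P[idx(i, j - 1)] - gap_open - gap_ext; tb = 1;
      }
      if (Q[idx(i, j - 1)] > NEG && Q[idx(i, j - 1)] - gap_ext > best) {
        best = Q[idx(i, j - 1)] - gap_ext; tb = 2;
      }
      if (tb >= 0) { Q[idx(i, j)] = best; tbQ[idx(i, j)] = tb; }
    }
  }

  int layer = 0;
  double score = M[idx(n, m)];
  if (n == 0 && m == 0) { layer = 0; score = 0.0; }
  if (P[idx(n, m)] > score) { score = P[idx(n, m)]; layer = 1; }
  if (Q[idx(n, m)] > score) { score = Q[idx(n, m)]; layer = 2; }

  std::string aa, bb;
  int i = n, j = m, ly = layer;
  while (i > 0 || j > 0) {
    signed char prev;
    if (ly == 0) {
      prev = tbM[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (ly == 1) {
      prev = tbP[idx(i, j)];
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      prev = tbQ[idx(i, j)];
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
    ly = prev;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = score);
}
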