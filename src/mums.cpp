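// Maximal unique match (MUM) detection between two sequences via a
// generalized suffix array with LCPs. A MUM is a maximal match whose
// substring occurs exactly once in each sequence: in suffix-array order
// it is an adjacent suffix pair, one from each sequence, whose pair LCP
// exceeds the LCPs with both outer neighbours (uniqueness) and whose
// preceding characters differ (left-maximality).

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <numeric>
#include <string>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".findMumsCpp")]]
DataFrame findMumsCpp(std::string a, std::string b, int minLen) {
  // N never matches anything, itself included: encode Ns (and other
  // ambiguity codes) with per-sequence sentinel characters.
  for (char& c : a) if (c != 'A' && c != 'C' && c != 'G' && c != 'T') c = 1;
  for (char& c : b) if (c != 'A' && c != 'C' && c != 'G' && c != 'T') c = 2;

  const size_t na = a.size(), nb = b.size();
  std::string s = a + '\x03' + b + '\x04';
  const size_t n = s.size();

  std::vector<int> sa(n);
  std::iota(sa.begin(), sa.end(), 0);
  const char* cs = s.c_str();
  std::sort(sa.begin(), sa.end(), [cs, n](int i, int j) {
    return std::strcmp(cs + i, cs + j) < 0;
  });

  // Kasai LCP: lcp[i] = longest common prefix of suffixes sa[i-1], sa[i]
  std::vector<int> rank(n), lcp(n, 0);
  for (size_t i = 0; i < n; ++i) rank[sa[i]] = (int)i;
  int h = 0;
  for (size_t i = 0; i < n; ++i) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && (size_t)(j + h) < n && s[i + h] == s[j + h]) ++h;
      lcp[rank[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }

  std::vector<int> startA, startB, lenOut;
  for (size_t i = 0; i + 1 < n; ++i) {
    int p = sa[i], q = sa[i + 1];
    bool pInA = (size_t)p < na, qInA = (size_t)q < na;
    if (pInA == qInA) continue;
    int l = lcp[i + 1];
    if (l < minLen) continue;
    // the length-l prefix must occur only at these two suffixes
    if ((int)lcp[i] >= l) continue;
    if (i + 2 < n && (int)lcp[i + 2] >= l) continue;
    // left-maximality
    if (p > 0 && q > 0 && s[p - 1] == s[q - 1]) continue;
    int pa = pInA ? p : q;
    int pb = pInA ? q : p;
    startA.push_back(pa);
    startB.push_back(pb - (int)na - 1);
    lenOut.push_back(l);
  }
  return DataFrame::create(_["start_a"] = startA, _["start_b"] = startB,
                           _["length"] = lenOut);
}
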