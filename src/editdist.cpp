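// Unit-cost Levenshtein distance (full and band-limited) and batched
// germline extension walks used by the annotator.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static int lev_full(const char* a, int la, const char* b, int lb) {
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      cur[j] = std::min(sub, std::min(prev[j], cur[j - 1]) + 1);
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// Banded Levenshtein: exact value if <= k, otherwise any value > k.
int lev_bounded(const char* a, int la, const char* b, int lb, int k) {
  if (std::abs(la - lb) > k) return k + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= std::min(lb, k); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - k), jhi = std::min(lb, i + k);
    cur[jlo - 1] = (jlo - 1 == 0) ? i : k + 1;
    int rowmin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      int del = (j <= i + k - 1) ? prev[j] + 1 : k + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
      rowmin = std::min(rowmin, cur[j]);
    }
    if (jhi < lb) cur[jhi + 1 <= lb ? jhi + 1 : lb] = k + 1;
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".lev_dist")]]
IntegerVector lev_dist(CharacterVector a, CharacterVector b) {
  int n = std::max(a.size(), b.size());
  if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
    stop("lengths of 'a' and 'b' must match or be 1");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, a.size() == 1 ? 0 : i));
    const char* sb = CHAR(STRING_ELT(b, b.size() == 1 ? 0 : i));
    out[i] = lev_full(sa, (int)strlen(sa), sb, (int)strlen(sb));
  }
  return out;
}

// Longest common prefix of read[start..] (1-based start) against ref,
// vectorised over reads. Used for the V-side germline extension walk.
// [[Rcpp::export(name = ".lcp_batch")]]
IntegerVector lcp_batch(CharacterVector reads, IntegerVector start,
                        CharacterVector refs) {
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* r = CHAR(STRING_ELT(reads, i));
    const char* g = CHAR(STRING_ELT(refs, i));
    int lr = (int)strlen(r), lg = (int)strlen(g);
    int s = start[i] - 1; // 0-based
    int m = 0;
    while (s + m < lr && m < lg && r[s + m] == g[m]) ++m;
    out[i] = m;
  }
  return out;
}

// Longest common suffix of read[..end] (1-based inclusive end) against
// the END of ref, vectorised. Used for the J-side walk (leftward).
// [[Rcpp::export(name = ".lcs_batch")]]
IntegerVector lcs_batch(CharacterVector reads, IntegerVector end,
                        CharacterVector refs) {
  int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* r = CHAR(STRING_ELT(reads, i));
    const char* g = CHAR(STRING_ELT(refs, i));
    int lg = (int)strlen(g);
    int e = end[i] - 1; // 0-based inclusive
    int m = 0;
    while (e - m >= 0 && m < lg && r[e - m] == g[lg - 1 - m]) ++m;
    out[i] = m;
  }
  return out;
}
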