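#ifndef STRAINMARK_NW_H
#define STRAINMARK_NW_H

#include <string>
#include <vector>
#include <cstdint>
#include <algorithm>

// Global alignment with free terminal gaps ("overlap" alignment), linear gap
// penalty.  Statistics cover the aligned region only: columns between the
// first and last aligned pair (terminal overhangs excluded) and the number of
// identical columns among them.
struct NwStats {
  long matches;   // identical aligned residue pairs
  long columns;   // alignment columns excluding terminal gaps
  long score;
};

struct NwAlignment {
  std::string a_aln;  // full-length aligned strings, terminal gaps included
  std::string b_aln;
  NwStats stats;
};

inline NwAlignment nw_overlap_align(const std::string& a, const std::string& b,
                                    int match, int mismatch, int gap) {
  const size_t n = a.size(), m = b.size();
  std::vector<long> prev(m + 1, 0), cur(m + 1, 0);
  std::vector<long> lastcol(n + 1, 0);
  // traceback: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<uint8_t> tb((n + 1) * (m + 1), 0);
  for (size_t j = 0; j <= m; ++j) tb[j] = 2;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = 0;
    tb[i * (m + 1)] = 1;
    for (size_t j = 1; j <= m; ++j) {
      long sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      long sup   = prev[j] + gap;
      long sleft = cur[j - 1] + gap;
      long best = sdiag; uint8_t dir = 0;
      if (sup > best)   { best = sup;   dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[i * (m + 1) + j] = dir;
    }
    lastcol[i] = cur[m];
    std::swap(prev, cur);
  }
  // best end over last row (prev) and last column (lastcol)
  long best = prev[m]; size_t bi = n, bj = m;
  for (size_t j = 0; j <= m; ++j)
    if (prev[j] > best) { best = prev[j]; bi = n; bj = j; }
  for (size_t i = 0; i <= n; ++i)
    if (lastcol[i] > best) { best = lastcol[i]; bi = i; bj = m; }

  NwAlignment out;
  out.stats.score = best;
  out.stats.matches = 0;
  out.stats.columns = 0;
  std::string ra, rb;
  // trailing overhang
  for (size_t i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (size_t j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  size_t i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t dir = tb[i * (m + 1) + j];
    if (dir == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) out.stats.matches++;
      --i; --j;
    } else if (dir == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
    out.stats.columns++;
  }
  // leading overhang
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  out.a_aln = ra;
  out.b_aln = rb;
  return out;
}

#endif
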