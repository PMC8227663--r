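#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

inline bool bases_equal(char a, char b) {
  int ca = base_code(a), cb = base_code(b);
  return ca >= 0 && ca == cb;  // N never matches anything
}

struct SeedEntry { int qpos; int strand; };  // strand +1 fwd, -1 revcomp

struct LocalAln {
  long score, matches, columns;
  int qs, qe, ss, se;  // 0-based half-open, window-local
  bool valid;
};

// Full Smith-Waterman with affine gaps (gap of length L costs
// -(open + L * ext)) over a bounded window, with traceback for identity.
LocalAln local_affine(const std::string& A, const std::string& B,
                      int match, int mismatch, int open, int ext) {
  const int n = (int)A.size(), m = (int)B.size();
  const long NEG = -1000000000L;
  // reused scratch: thousands of small refinements per query otherwise
  // churn the allocator
  static std::vector<long> H, E, F;
  static std::vector<uint8_t> tH, tE, tF;
  size_t need = (size_t)(n + 1) * (m + 1);
  H.assign(need, 0); E.assign(need, NEG); F.assign(need, NEG);
  tH.assign(need, 0);  // 0 stop, 1 diag, 2 E, 3 F
  tE.assign(need, 0);  // 0 open, 1 extend
  tF.assign(need, 0);
  long best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * (m + 1) + j;
      size_t up = c - (m + 1), left = c - 1, diag = up - 1;
      long eo = H[left] - open - ext, ee = E[left] - ext;
      E[c] = std::max(eo, ee); tE[c] = ee > eo ? 1 : 0;
      long fo = H[up] - open - ext, fe = F[up] - ext;
      F[c] = std::max(fo, fe); tF[c] = fe > fo ? 1 : 0;
      long sd = H[diag] + (bases_equal(A[i - 1], B[j - 1]) ? match : mismatch);
      long h = 0; uint8_t d = 0;
      if (sd > h) { h = sd; d = 1; }
      if (E[c] > h) { h = E[c]; d = 2; }
      if (F[c] > h) { h = F[c]; d = 3; }
      H[c] = h; tH[c] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  LocalAln out; out.valid = best > 0;
  out.score = best; out.matches = 0; out.columns = 0;
  out.qe = bi; out.se = bj;
  int i = bi, j = bj, state = 0;  // 0 = H
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t d = tH[c];
      if (d == 0) break;
      if (d == 1) {
        if (bases_equal(A[i - 1], B[j - 1])) out.matches++;
        out.columns++; --i; --j;
      } else if (d == 2) state = 2;
      else state = 3;
    } else if (state == 2) {      // E: gap in A, consume B
      out.columns++;
      if (tE[c] == 0) state = 0;
      --j;
    } else {                      // F: gap in B, consume A
      out.columns++;
      if (tF[c] == 0) state = 0;
      --i;
    }
  }
  out.qs = i; out.ss = j;
  return out;
}

} // namespace

//' Seeded BLASTN-like search of one query against subject sequences
//'
//' Exact word seeds on both strands are extended ungapped with an X-drop
//' rule, then locally realigned with affine gaps over a padded window to
//' obtain final span, length and identity.  A hit is reported when the
//' refined alignment reaches `min_len` columns at `min_id` identity, or when
//' the maximal exact run through the seed reaches `exact_min` bases.
//'
//' @param query query sequence (ACGTN)
//' @param subjects character vector of subject sequences
//' @param word_size exact seed length
//' @param match,mismatch,gap_open,gap_ext alignment scores (penalties
//'   positive for gaps; a gap of length L costs gap_open + L * gap_ext)
//' @param xdrop ungapped extension drop-off
//' @param min_len,min_id,exact_min hit definition
//' @return data.frame of hits (0-based half-open spans; subject strand)
//' @keywords internal
// [[Rcpp::export]]
DataFrame screen_query_cpp(std::string query, CharacterVector subjects,
                           int word_size = 11, int match = 2, int mismatch = -3,
                           int gap_open = 5, int gap_ext = 2, int xdrop = 20,
                           int min_len = 60, double min_id = 0.8,
                           int exact_min = 25) {
  const int qlen = (int)query.size();
  const int k = word_size;
  std::string rc(query.rbegin(), query.rend());
  for (auto& ch : rc) ch = comp_base(ch);

  // k-mer index over both query strands (2-bit encoded, k <= 15), plus a
  // bitmap prefilter so subject scanning rarely touches the hash map
  std::unordered_map<uint32_t, std::vector<SeedEntry> > index;
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;
  std::vector<uint64_t> bitmap(k <= 15 ? ((size_t)1 << (2 * k - 6)) + 1 : 1,
                               0);
  for (int strand = 0; strand < 2; ++strand) {
    const std::string& Q = strand == 0 ? query : rc;
    uint32_t w = 0; int run = 0;
    for (int p = 0; p < (int)Q.size(); ++p) {
      int c = base_code(Q[p]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run >= k) {
        SeedEntry e; e.qpos = p - k + 1; e.strand = strand == 0 ? 1 : -1;
        index[w].push_back(e);
        bitmap[w >> 6] |= (uint64_t)1 << (w & 63u);
      }
    }
  }

  std::vector<int> r_subject, r_qs, r_qe, r_ss, r_se, r_len, r_exact;
  std::vector<double> r_id, r_score;
  std::vector<std::string> r_strand;

  for (int si = 0; si < subjects.size(); ++si) {
    std::string S = as<std::string>(subjects[si]);
    const int slen = (int)S.size();
    // (strand, diagonal) -> subject end already covered by an extension
    std::unordered_map<int64_t, int> covered;
    uint32_t w = 0; int run = 0;
    for (int p = 0; p < slen; ++p) {
      int c = base_code(S[p]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)c) & mask;
      if (++run < k) continue;
      if (!(bitmap[w >> 6] & ((uint64_t)1 << (w & 63u)))) continue;
      auto it = index.find(w);
      if (it == index.end()) continue;
      const int s0 = p - k + 1;
      for (const SeedEntry& e : it->second) {
        const std::string& Q = e.strand == 1 ? query : rc;
        const int q0 = e.qpos;
        int64_t key = ((int64_t)(e.strand == 1 ? 0 : 1) << 62) ^
                      ((int64_t)(s0 - q0 + qlen) << 1);
        auto cov = covered.find(key);
        if (cov != covered.end() && s0 < cov->second) continue;

        // ungapped X-drop extension
        long sc = (long)k * match, bestsc = sc;
        int qi = q0 + k, sj = s0 + k, qe = qi, se = sj;
        long mt = k;  // matched bases on best path (seed is exact)
        long mt_run = k, mt_best = k;
        while (qi < qlen && sj < slen) {
          sc += bases_equal(Q[qi], S[sj]) ? match : mismatch;
          if (bases_equal(Q[qi], S[sj])) mt_run++;
          ++qi; ++sj;
          if (sc > bestsc) { bestsc = sc; qe = qi; se = sj; mt_best = mt_run; }
          if (bestsc - sc > xdrop) break;
        }
        mt = mt_best;
        long right_best = bestsc;
        sc = right_best; bestsc = right_best;
        int qs = q0, ss = s0; qi = q0 - 1; sj = s0 - 1;
        mt_run = mt; mt_best = mt;
        while (qi >= 0 && sj >= 0) {
          sc += bases_equal(Q[qi], S[sj]) ? match : mismatch;
          if (bases_equal(Q[qi], S[sj])) mt_run++;
          if (sc > bestsc) { bestsc = sc; qs = qi; ss = sj; mt_best = mt_run; }
          --qi; --sj;
          if (bestsc - sc > xdrop) break;
        }
        mt = mt_best;

        // maximal exact run through the seed
        int el = 0, er = 0;
        while (q0 - 1 - el >= 0 && s0 - 1 - el >= 0 &&
               bases_equal(Q[q0 - 1 - el], S[s0 - 1 - el])) ++el;
        while (q0 + k + er < qlen && s0 + k + er < slen &&
               bases_equal(Q[q0 + k + er], S[s0 + k + er])) ++er;
        int exact_run = k + el + er;

        int cov_end = se;
        long cols = qe - qs, mats = mt, score = bestsc;
        int hqs = qs, hqe = qe, hss = ss, hse = se;

        // gapped refinement over a padded window; only worthwhile when the
        // ungapped extension suggests genuine homology (chance seeds die
        // within a few bases and can never satisfy the hit definition).
        // Area-capped: oversized windows only arise for long near-exact
        // extensions whose ungapped statistics are already decisive.
        const int pad = 40;
        bool promising = cols >= (long)(0.6 * min_len) ||
                         exact_run >= std::min(exact_min, 15);
        int wqs = std::max(0, qs - pad), wqe = std::min(qlen, qe + pad);
        int wss = std::max(0, ss - pad), wse = std::min(slen, se + pad);
        double area = (double)(wqe - wqs) * (double)(wse - wss);
        if (promising && area <= 1.5e6) {
          LocalAln la = local_affine(Q.substr(wqs, wqe - wqs),
                                     S.substr(wss, wse - wss),
                                     match, mismatch, gap_open, gap_ext);
          if (la.valid) {
            cols = la.columns; mats = la.matches; score = la.score;
            hqs = wqs + la.qs; hqe = wqs + la.qe;
            hss = wss + la.ss; hse = wss + la.se;
            cov_end = std::max(cov_end, hse);
          }
        }
        covered[key] = cov_end;

        bool is_hit = (cols >= min_len && cols > 0 &&
                       (double)mats / (double)cols >= min_id) ||
                      exact_run >= exact_min;
        if (!is_hit) continue;

        // map back to original query coordinates for the reverse strand
        int oqs = hqs, oqe = hqe;
        if (e.strand == -1) { oqs = qlen - hqe; oqe = qlen - hqs; }
        r_subject.push_back(si + 1);
        r_qs.push_back(oqs); r_qe.push_back(oqe);
        r_ss.push_back(hss); r_se.push_back(hse);
        r_strand.push_back(e.strand == 1 ? "+" : "-");
        r_len.push_back((int)cols);
        r_id.push_back(cols > 0 ? (double)mats / (double)cols : 0.0);
        r_score.push_back((double)score);
        r_exact.push_back(exact_run);
      }
    }
  }

  return DataFrame::create(
      _["subject"] = r_subject, _["qstart"] = r_qs, _["qend"] = r_qe,
      _["sstart"] = r_ss, _["send"] = r_se, _["strand"] = r_strand,
      _["length"] = r_len, _["identity"] = r_id, _["score"] = r_score,
      _["exact_run"] = r_exact, _["stringsAsFactors"] = false);
}
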