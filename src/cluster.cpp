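#include <Rcpp.h>
#include <unordered_map>
#include "nw.h"
using namespace Rcpp;

namespace {

// FNV-1a over k bytes
inline uint64_t hash_kmer(const char* s, int k) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < k; ++i) {
    h ^= (uint64_t)(unsigned char)s[i];
    h *= 1099511628211ULL;
  }
  return h;
}

} // namespace

//' Greedy centroid clustering of protein sequences
//'
//' Sequences must arrive pre-sorted (length descending, ties resolved by the
//' caller).  Each sequence joins the earliest-founded centroid whose
//' overlap-alignment identity reaches `min_id` and whose length ratio
//' (shorter/longer) reaches `min_len_ratio`; otherwise it founds a new
//' centroid.  A k-mer inverted index over centroids prunes the candidate set;
//' a centroid sharing no k-mer with the query cannot plausibly reach 90%
//' identity at gene scale, and sequences shorter than k fall back to a full
//' scan.
//'
//' @param seqs character vector of amino-acid sequences, pre-sorted
//' @param min_id minimum identity (matches / columns excl. terminal gaps)
//' @param min_len_ratio minimum shorter/longer length ratio
//' @param k word length of the candidate index
//' @return 1-based integer centroid assignment per sequence
//' @keywords internal
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double min_id = 0.9,
                                 double min_len_ratio = 0.7, int k = 6) {
  const int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> cent;            // centroid sequences
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<int> stamp;                   // per-centroid last-seen marker
  std::vector<int> shared;                  // shared k-mer count this query
  int stamp_val = 0;

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int len = (int)s.size();
    ++stamp_val;

    std::vector<int> cand;
    if (len >= k) {
      for (int p = 0; p + k <= len; ++p) {
        uint64_t h = hash_kmer(s.data() + p, k);
        auto it = index.find(h);
        if (it == index.end()) continue;
        for (int c : it->second) {
          if (stamp[c] != stamp_val) {
            stamp[c] = stamp_val;
            shared[c] = 1;
            cand.push_back(c);
          } else ++shared[c];
        }
      }
      // a >= min_id match shares a large fraction of its k-mers; isolated
      // chance collisions do not warrant an alignment
      int need = std::max(3, (int)(0.05 * (len - k + 1)));
      std::vector<int> keep;
      for (int c : cand) if (shared[c] >= need) keep.push_back(c);
      cand.swap(keep);
      std::sort(cand.begin(), cand.end());
    } else {
      for (int c = 0; c < (int)cent.size(); ++c) cand.push_back(c);
    }

    int hit = -1;
    for (int c : cand) {
      const std::string& cs = cent[c];
      double lmin = (double)std::min((size_t)len, cs.size());
      double lmax = (double)std::max((size_t)len, cs.size());
      if (lmax == 0 || lmin / lmax < min_len_ratio) continue;
      if (s == cs) { hit = c; break; }  // identical: identity 1, full cover
      NwAlignment aln = nw_overlap_align(s, cs, 1, -1, -2);
      // coverage gate: a free-end-gap alignment of unrelated sequences can
      // be a short high-identity overlap; demand the aligned region span
      // most of the shorter sequence before the identity test applies
      if (aln.stats.columns >= min_len_ratio * lmin &&
          (double)aln.stats.matches / (double)aln.stats.columns >= min_id) {
        hit = c;
        break;
      }
    }

    if (hit < 0) {
      hit = (int)cent.size();
      cent.push_back(s);
      stamp.push_back(stamp_val);
      shared.push_back(0);
      if (len >= k) {
        // insert each distinct k-mer once
        std::unordered_map<uint64_t, bool> seen;
        for (int p = 0; p + k <= len; ++p) {
          uint64_t h = hash_kmer(s.data() + p, k);
          if (seen.emplace(h, true).second) index[h].push_back(hit);
        }
      }
    }
    assign[i] = hit + 1;
  }
  return assign;
}
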