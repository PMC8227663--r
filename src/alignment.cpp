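#include <Rcpp.h>
#include "nw.h"
using namespace Rcpp;

//' Overlap-alignment statistics for a pair of sequences
//'
//' Global alignment with free terminal gaps and a linear gap penalty.
//' Used for gene-to-centroid identity during family clustering and for
//' per-gene core alignments during SNP calling.
//'
//' @param a,b sequences (single strings, any alphabet)
//' @param match,mismatch,gap integer scores (gap applied per gapped column)
//' @return list with `matches`, `columns` (terminal gaps excluded) and `score`
//' @keywords internal
// [[Rcpp::export]]
List nw_stats_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1, int gap = -2) {
  NwAlignment aln = nw_overlap_align(a, b, match, mismatch, gap);
  return List::create(_["matches"] = (double)aln.stats.matches,
                      _["columns"] = (double)aln.stats.columns,
                      _["score"]   = (double)aln.stats.score);
}

//' Overlap alignment returning full aligned strings
//'
//' Terminal overhangs are represented as gap columns so each input position
//' appears exactly once in its aligned string.
//'
//' @inheritParams nw_stats_cpp
//' @return character vector of the two aligned strings
//' @keywords internal
// [[Rcpp::export]]
CharacterVector nw_align_cpp(std::string a, std::string b,
                             int match = 1, int mismatch = -1, int gap = -2) {
  NwAlignment aln = nw_overlap_align(a, b, match, mismatch, gap);
  return CharacterVector::create(aln.a_aln, aln.b_aln);
}
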