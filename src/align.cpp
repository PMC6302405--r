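#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Exhaustive gapless overlap scan for one read pair.
//
// Coordinates: `offset` is the 0-based position of the 5' end of the
// reverse-complemented R2 on R1's axis.  The overlap is the intersection
// of [0, len1) and [offset, offset + len2).  Dovetail <=> offset < 0
// (R2 3' overhang left of R1's 5' end) or len1 - offset > len2 (R1 3'
// overhang beyond R2's 5' end).

struct Score {
  int matches, mismatches, npos, overlap;
};

static inline Score score_at(const char* s1, int len1, const char* s2,
                             int len2, int offset) {
  int lo = offset > 0 ? offset : 0;
  int hi = std::min(len1, offset + len2);
  Score sc{0, 0, 0, hi - lo};
  for (int i = lo; i < hi; ++i) {
    char a = s1[i], b = s2[i - offset];
    if (a == 'N' || b == 'N')
      ++sc.npos;          // ambiguous bases: neither match nor mismatch
    else if (a == b)
      ++sc.matches;
    else
      ++sc.mismatches;
  }
  return sc;
}

static inline bool is_dovetail(int offset, int len1, int len2) {
  return offset < 0 || len1 - offset > len2;
}

// strictly better under: min mismatch fraction (over non-N columns),
// then larger overlap, then smaller |offset|, then non-negative offset
static bool better(const Score& a, int off_a, const Score& b, int off_b) {
  int64_t da = a.matches + a.mismatches, db = b.matches + b.mismatches;
  int64_t fa = (int64_t)a.mismatches * db, fb = (int64_t)b.mismatches * da;
  if (fa != fb) return fa < fb;
  if (a.overlap != b.overlap) return a.overlap > b.overlap;
  int aa = off_a < 0 ? -off_a : off_a, ab = off_b < 0 ? -off_b : off_b;
  if (aa != ab) return aa < ab;
  return off_a > off_b;
}

// [[Rcpp::export]]
IntegerVector cpp_score_overlap(std::string seq1, std::string rc2,
                                int offset) {
  int len1 = seq1.size(), len2 = rc2.size();
  Score sc = score_at(seq1.c_str(), len1, rc2.c_str(), len2, offset);
  if (sc.overlap <= 0)
    stop("offset %d implies zero overlap for lengths %d/%d", offset, len1,
         len2);
  return IntegerVector::create(_["matches"] = sc.matches,
                               _["mismatches"] = sc.mismatches,
                               _["n_positions"] = sc.npos,
                               _["overlap_len"] = sc.overlap);
}

// [[Rcpp::export]]
List cpp_best_alignments(CharacterVector seq1, CharacterVector rc2,
                         int min_overlap, double max_mismatch_frac,
                         bool allow_dovetail) {
  int n = seq1.size();
  if (rc2.size() != n) stop("seq1 and rc2 must have equal length");
  LogicalVector found(n);
  IntegerVector off(n, NA_INTEGER), ov(n, NA_INTEGER), mat(n, NA_INTEGER),
      mis(n, NA_INTEGER), npos(n, NA_INTEGER);
  for (int k = 0; k < n; ++k) {
    const char* s1 = CHAR(STRING_ELT(seq1, k));
    const char* s2 = CHAR(STRING_ELT(rc2, k));
    int len1 = LENGTH(STRING_ELT(seq1, k));
    int len2 = LENGTH(STRING_ELT(rc2, k));
    bool have = false;
    Score best{0, 0, 0, 0};
    int best_off = 0;
    int lo = min_overlap - len2, hi = len1 - min_overlap;
    for (int o = lo; o <= hi; ++o) {
      if (!allow_dovetail && is_dovetail(o, len1, len2)) continue;
      int olap = std::min(len1, o + len2) - std::max(0, o);
      if (olap < min_overlap) continue;
      Score sc = score_at(s1, len1, s2, len2, o);
      int den = sc.matches + sc.mismatches;
      if (sc.mismatches > max_mismatch_frac * den + 1e-9) continue;
      if (!have || better(sc, o, best, best_off)) {
        best = sc;
        best_off = o;
        have = true;
      }
    }
    found[k] = have;
    if (have) {
      off[k] = best_off;
      ov[k] = best.overlap;
      mat[k] = best.matches;
      mis[k] = best.mismatches;
      npos[k] = best.npos;
    }
  }
  return List::create(_["found"] = found, _["offset"] = off,
                      _["overlap_len"] = ov, _["matches"] = mat,
                      _["mismatches"] = mis, _["n_positions"] = npos);
}
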