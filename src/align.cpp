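#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Ungapped semi-global alignment of each reference segment against each
// query: the reference is slid over the query at every offset (negative
// offsets hang the reference off the query 5' end), the overlap is scored
// +1 per match / -1 per mismatch (query 'N' scores 0), and the best-scoring
// offset is kept. No internal gaps: rearranged, unmutated sequences differ
// from germline only by end-trimming and untemplated insertions, which this
// sliding model captures exactly.
//
// `mode` accounts for exonucleolytic end-trimming of the germline segment:
//   0 = score the whole overlap;
//   1 = V mode: the reference 3' end may be trimmed away, so take the best
//       prefix of the overlap (length >= min_overlap) without penalizing
//       the trimmed remainder;
//   2 = J mode: the reference 5' end may be trimmed, so take the best
//       suffix of the overlap.
//
// Returns a list with integer matrices `score` and `shift`
// (n_query x n_ref); shift is the 0-based query position of reference
// position 0 (may be negative). Ties keep the smallest shift.
// [[Rcpp::export(name = ".align_ungapped")]]
List align_ungapped(CharacterVector queries, CharacterVector refs,
                    int min_overlap = 10, int mode = 0) {
  const int nq = queries.size(), nr = refs.size();
  IntegerMatrix score(nq, nr), shift(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    const int lq = q.size();
    for (int j = 0; j < nr; ++j) {
      const std::string &r = rs[j];
      const int lr = r.size();
      int best = NA_INTEGER, bestShift = NA_INTEGER;
      for (int s = -(lr - min_overlap); s <= lq - min_overlap; ++s) {
        const int qs = s > 0 ? s : 0;
        const int rs0 = s > 0 ? 0 : -s;
        int len = std::min(lq - qs, lr - rs0);
        if (len < min_overlap) continue;
        int sc;
        const char *qp = q.data() + qs, *rp = r.data() + rs0;
        if (mode == 1) {
          // best prefix sum with prefix length >= min_overlap
          int run = 0; sc = INT_MIN;
          for (int k = 0; k < len; ++k) {
            const char qc = qp[k];
            if (qc != 'N') run += (qc == rp[k]) ? 1 : -1;
            if (k + 1 >= min_overlap && run > sc) sc = run;
          }
        } else if (mode == 2) {
          // best suffix sum with suffix length >= min_overlap
          int run = 0; sc = INT_MIN;
          for (int k = len - 1; k >= 0; --k) {
            const char qc = qp[k];
            if (qc != 'N') run += (qc == rp[k]) ? 1 : -1;
            if (len - k >= min_overlap && run > sc) sc = run;
          }
        } else {
          sc = 0;
          for (int k = 0; k < len; ++k) {
            const char qc = qp[k];
            if (qc == 'N') continue;
            sc += (qc == rp[k]) ? 1 : -1;
          }
        }
        if (best == NA_INTEGER || sc > best) { best = sc; bestShift = s; }
      }
      score(i, j) = best;
      shift(i, j) = bestShift;
    }
  }
  return List::create(_["score"] = score, _["shift"] = shift);
}

// Scan the reading frame anchored at `from0` (0-based, inclusive) for stop
// codons in [from0, to0): only codons lying entirely inside the window are
// examined. Returns a logical vector, NA where the window is invalid.
// [[Rcpp::export(name = ".has_stop_in_frame")]]
LogicalVector has_stop_in_frame(CharacterVector seqs, IntegerVector from0,
                                IntegerVector to0) {
  const int n = seqs.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string s = as<std::string>(seqs[i]);
    const int a = from0[i], b = std::min<int>(to0[i], s.size());
    if (a == NA_INTEGER || a < 0 || b <= a) { out[i] = NA_LOGICAL; continue; }
    bool hit = false;
    for (int p = a; p + 3 <= b; p += 3) {
      if (s[p] == 'T') {
        const char c2 = s[p + 1], c3 = s[p + 2];
        if ((c2 == 'A' && (c3 == 'A' || c3 == 'G')) ||
            (c2 == 'G' && c3 == 'A')) { hit = true; break; }
      }
    }
    out[i] = hit;
  }
  return out;
}
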