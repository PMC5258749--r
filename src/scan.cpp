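#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive ungapped scan: every placement of `pattern` fully inside `text`
// with at most `max_mm` mismatches. Positions are 1-based. Any character
// inequality (including N against anything) counts as a mismatch.
// [[Rcpp::export]]
List mismatch_scan_cpp(const std::string& text, const std::string& pattern, int max_mm) {
  const int n = (int)text.size(), m = (int)pattern.size();
  std::vector<int> starts, counts;
  std::vector<std::vector<int> > allpos;
  if (m > 0 && m <= n) {
    for (int s = 0; s + m <= n; ++s) {
      int mm = 0;
      for (int k = 0; k < m; ++k) {
        if (text[s + k] != pattern[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) {
        starts.push_back(s + 1);
        counts.push_back(mm);
        std::vector<int> pos;
        for (int k = 0; k < m; ++k)
          if (text[s + k] != pattern[k]) pos.push_back(k + 1);
        allpos.push_back(pos);
      }
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["mismatches"] = wrap(counts),
                      _["positions"] = wrap(allpos));
}

// Best (fewest mismatches, then leftmost) placement of `pattern` fully inside
// `text`. Returns c(start, mismatches), or c(-1, -1) when pattern is longer
// than text or empty.
// [[Rcpp::export]]
IntegerVector best_placement_cpp(const std::string& text, const std::string& pattern) {
  const int n = (int)text.size(), m = (int)pattern.size();
  int best_s = -1, best_mm = -1;
  if (m > 0 && m <= n) {
    for (int s = 0; s + m <= n; ++s) {
      int mm = 0;
      for (int k = 0; k < m; ++k) {
        if (text[s + k] != pattern[k]) {
          ++mm;
          if (best_mm >= 0 && mm >= best_mm) break;
        }
      }
      if (best_mm < 0 || mm < best_mm) { best_mm = mm; best_s = s + 1; }
      if (best_mm == 0) break;
    }
  }
  return IntegerVector::create(best_s, best_mm);
}

// All ungapped placements of `query` against `subject`, allowing the query to
// overhang either end, restricted to overlaps of at least `min_span` and
// identity (matches/span) of at least `min_identity`. Used by the
// contamination, expression and repeat-coverage screens.
// [[Rcpp::export]]
DataFrame ungapped_hits_cpp(const std::string& query, const std::string& subject,
                            int min_span, double min_identity) {
  const int lq = (int)query.size(), ls = (int)subject.size();
  std::vector<int> qs, qe, ss, se, span_v, match_v;
  if (min_span < 1) min_span = 1;
  // offset d: subject position aligned with query position 1 is d + 1
  for (int d = -(lq - min_span); d <= ls - min_span; ++d) {
    int q0 = std::max(0, -d);            // 0-based first aligned query pos
    int q1 = std::min(lq, ls - d);       // one past last aligned query pos
    int span = q1 - q0;
    if (span < min_span) continue;
    int matches = 0;
    for (int k = q0; k < q1; ++k)
      if (query[k] == subject[k + d]) ++matches;
    if ((double)matches / span + 1e-12 < min_identity) continue;
    qs.push_back(q0 + 1); qe.push_back(q1);
    ss.push_back(q0 + d + 1); se.push_back(q1 + d);
    span_v.push_back(span); match_v.push_back(matches);
  }
  return DataFrame::create(_["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
                           _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
                           _["span"] = wrap(span_v), _["matches"] = wrap(match_v));
}
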