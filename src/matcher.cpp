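#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Sliding-window Hamming matcher: a query matches a payload if some window
// of the payload of the query's length has Hamming distance <= max_mismatch
// (substitutions only, no indels).  A read is assigned to an aptamer when
// queries of exactly one aptamer match; queries of two or more distinct
// aptamers -> ambiguous; none -> unassigned.
//
// Returns parallel vectors: aptamer index (1-based; 0 = unassigned,
// -1 = ambiguous), and for assigned reads the matched query index,
// mismatch count and 1-based match position (minimal mismatch count,
// then leftmost position, then lowest query index).
// [[Rcpp::export]]
List cpp_match_reads(CharacterVector payloads, CharacterVector queries,
                     IntegerVector query_aptamer, int n_aptamers,
                     int max_mismatch) {
  const int n = payloads.size(), nq = queries.size();
  std::vector<std::string> qs(nq);
  for (int j = 0; j < nq; ++j) qs[j] = as<std::string>(queries[j]);

  IntegerVector apt(n), qidx(n, NA_INTEGER), mism(n, NA_INTEGER),
      pos(n, NA_INTEGER);
  std::vector<int> best_mm(n_aptamers), best_pos(n_aptamers),
      best_q(n_aptamers);
  std::vector<char> hit(n_aptamers);

  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(payloads, i);
    const char *p = CHAR(s);
    const int L = LENGTH(s);
    std::fill(hit.begin(), hit.end(), 0);
    int n_hit = 0, the_apt = -1;

    for (int j = 0; j < nq; ++j) {
      const std::string &q = qs[j];
      const int k = (int)q.size();
      const int a = query_aptamer[j] - 1;
      for (int w = 0; w + k <= L; ++w) {
        int d = 0;
        const char *win = p + w;
        for (int t = 0; t < k; ++t) {
          if (win[t] != q[t] && ++d > max_mismatch) break;
        }
        if (d <= max_mismatch) {
          if (!hit[a]) {
            hit[a] = 1;
            ++n_hit;
            the_apt = a;
            best_mm[a] = INT_MAX;
          }
          if (d < best_mm[a] ||
              (d == best_mm[a] && (w < best_pos[a] ||
               (w == best_pos[a] && j < best_q[a])))) {
            best_mm[a] = d;
            best_pos[a] = w;
            best_q[a] = j;
          }
        }
      }
    }
    if (n_hit == 0) {
      apt[i] = 0;
    } else if (n_hit > 1) {
      apt[i] = -1;
    } else {
      apt[i] = the_apt + 1;
      qidx[i] = best_q[the_apt] + 1;
      mism[i] = best_mm[the_apt];
      pos[i] = best_pos[the_apt] + 1;
    }
  }
  return List::create(_["aptamer"] = apt, _["query_index"] = qidx,
                      _["mismatches"] = mism, _["position"] = pos);
}
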