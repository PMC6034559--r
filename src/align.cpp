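#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty.
//
// Deterministic by construction:
//  * the reported cell is the maximal-scoring cell with the smallest query
//    end, ties broken by the smallest subject end (row-major scan order);
//  * traceback prefers diagonal, then up (gap in subject), then left
//    (gap in query).
// Identity is computed over all alignment columns (gap columns count as
// non-matching); query coverage is the aligned query span over the full
// query length. Coordinates are 0-based half-open on the input strings.
//
// The DP is templated on the score type: integer scoring parameters (the
// default +1/-1/-2) run in the faster integer kernel, anything else falls
// back to doubles.

template <typename T>
static List sw_align_run(const std::string& query, const std::string& subject,
                         T match, T mismatch, T gap) {
  const int n = (int) query.size();
  const int m = (int) subject.size();

  std::vector<T> prev(m + 1, T(0)), curr(m + 1, T(0));
  // traceback codes: 0 stop, 1 diagonal, 2 up, 3 left
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  T best = T(0);
  int bi = 0, bj = 0;
  const char* q = query.data();
  const char* s = subject.data();

  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    unsigned char* tbrow = &tb[(size_t) i * (m + 1)];
    curr[0] = T(0);
    for (int j = 1; j <= m; ++j) {
      const T diag = prev[j - 1] + (qc == s[j - 1] ? match : mismatch);
      const T up = prev[j] + gap;
      const T left = curr[j - 1] + gap;
      T h = T(0);
      unsigned char code = 0;
      // preference order on equal scores: diagonal, up, left, stop
      if (diag >= up && diag >= left && diag > T(0)) {
        h = diag; code = 1;
      } else if (up >= left && up > T(0)) {
        h = up; code = 2;
      } else if (left > T(0)) {
        h = left; code = 3;
      }
      curr[j] = h;
      tbrow[j] = code;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(prev, curr);
  }

  if (best <= T(0)) return List::create(Named("score") = 0.0);

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  while (i > 0 && j > 0) {
    unsigned char code = tb[(size_t) i * (m + 1) + j];
    if (code == 0) break;
    ++columns;
    if (code == 1) {
      if (q[i - 1] == s[j - 1]) ++matches;
      --i; --j;
    } else if (code == 2) {
      --i;
    } else {
      --j;
    }
  }
  const int qstart = i, qend = bi, sstart = j, send = bj;

  return List::create(
    Named("score") = (double) best,
    Named("identity") = 100.0 * matches / columns,
    Named("query_coverage") = 100.0 * (qend - qstart) / n,
    Named("matches") = matches,
    Named("columns") = columns,
    Named("qstart") = qstart, Named("qend") = qend,
    Named("sstart") = sstart, Named("send") = send);
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match, double mismatch, double gap) {
  if (query.empty() || subject.empty()) stop("empty sequence");
  const bool integral =
    match == std::floor(match) && mismatch == std::floor(mismatch) &&
    gap == std::floor(gap) && std::abs(match) < 1e6 &&
    std::abs(mismatch) < 1e6 && std::abs(gap) < 1e6;
  if (integral) {
    return sw_align_run<long>(query, subject, (long) match, (long) mismatch,
                              (long) gap);
  }
  return sw_align_run<double>(query, subject, match, mismatch, gap);
}
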