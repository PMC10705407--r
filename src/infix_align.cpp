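#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Infix (semi-global) unit-cost edit-distance alignment of a query against a
// segment: the query is consumed in full, the segment's flanks are free.
// Among all minimum-distance placements the leftmost segment start is chosen
// (then the leftmost end); within a placement the traceback prefers
// diagonal > up (gap in segment) > left (gap in query) among moves that are
// distance-optimal and preserve the minimal start.
//
// Returns: edit distance, 0-based start/end columns of the placement, and for
// each query position the 0-based segment column it is matched/mismatched to
// (NA for query positions consumed by a gap column).
// [[Rcpp::export(name = ".infix_align_cpp")]]
List infix_align_cpp(std::string query, std::string segment) {
  const int n = query.size(), m = segment.size();
  if (n == 0 || m == 0) stop("empty sequence");
  // D: edit distance; S: minimal start column among D-optimal paths
  std::vector<int> D((n + 1) * (m + 1)), S((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int j = 0; j <= m; ++j) { D[at(0, j)] = 0; S[at(0, j)] = j; }
  for (int i = 1; i <= n; ++i) {
    D[at(i, 0)] = i;
    S[at(i, 0)] = 0;
    for (int j = 1; j <= m; ++j) {
      int cost = (tolower(query[i - 1]) == tolower(segment[j - 1])) ? 0 : 1;
      int dDiag = D[at(i - 1, j - 1)] + cost;
      int dUp   = D[at(i - 1, j)] + 1;   // gap in segment (query char unplaced)
      int dLeft = D[at(i, j - 1)] + 1;   // gap in query
      int d = std::min(dDiag, std::min(dUp, dLeft));
      int s = INT_MAX;
      if (dDiag == d) s = std::min(s, S[at(i - 1, j - 1)]);
      if (dUp   == d) s = std::min(s, S[at(i - 1, j)]);
      if (dLeft == d) s = std::min(s, S[at(i, j - 1)]);
      D[at(i, j)] = d;
      S[at(i, j)] = s;
    }
  }
  // best end column: min distance, then min start, then leftmost end
  int bj = 0, bd = INT_MAX, bs = INT_MAX;
  for (int j = 0; j <= m; ++j) {
    int d = D[at(n, j)], s = S[at(n, j)];
    if (d < bd || (d == bd && (s < bs))) { bd = d; bs = s; bj = j; }
  }
  // traceback
  IntegerVector map(n, NA_INTEGER);
  int i = n, j = bj;
  while (i > 0) {
    int d = D[at(i, j)], s = S[at(i, j)];
    int cost = (j > 0 && tolower(query[i - 1]) == tolower(segment[j - 1])) ? 0 : 1;
    if (j > 0 && D[at(i - 1, j - 1)] + cost == d && S[at(i - 1, j - 1)] == s) {
      map[i - 1] = j - 1; --i; --j;
    } else if (D[at(i - 1, j)] + 1 == d && S[at(i - 1, j)] == s) {
      --i;
    } else if (j > 0 && D[at(i, j - 1)] + 1 == d && S[at(i, j - 1)] == s) {
      --j;
    } else if (j > 0 && D[at(i - 1, j - 1)] + cost == d) {
      map[i - 1] = j - 1; --i; --j;  // start bookkeeping exhausted; stay optimal
    } else if (D[at(i - 1, j)] + 1 == d) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["distance"] = bd, _["start"] = bs, _["end"] = bj,
                      _["map"] = map);
}
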