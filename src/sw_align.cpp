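#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) of a query read against a subject
// element sequence.  A gap run of length L scores gap_open + L * gap_extend
// (both penalties negative), matching the convention of
// Biostrings::pairwiseAlignment(gapOpening, gapExtension).
//
// Traceback is deterministic: the end cell is the first maximal H cell in
// row-major scan order (query index outer), and at each step the preferred
// predecessor is diagonal > gap-in-query (subject consumed) > gap-in-subject
// (query consumed).
//
// Returns an integer vector:
//   score, mismatches, gap columns (inserted + deleted bases),
//   query start/end, subject start/end (1-based, inclusive; 0s if score 0).
// [[Rcpp::export(name = ".sw_align_cpp")]]
IntegerVector sw_align_cpp(std::string query, std::string subject,
                           int match, int mismatch,
                           int gap_open, int gap_extend) {
  const int m = query.size(), n = subject.size();
  const int NEG = INT_MIN / 4;
  const int go = gap_open + gap_extend;  // cost of opening a 1-base gap
  // H: best overall; E: ends with gap in query (consumes subject);
  // F: ends with gap in subject (consumes query).
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] + go, E[at(i, j - 1)] + gap_extend);
      int f = std::max(H[at(i - 1, j)] + go, F[at(i - 1, j)] + gap_extend);
      int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      int h = H[at(i - 1, j - 1)] + s;
      h = std::max(std::max(h, std::max(e, f)), 0);
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  IntegerVector out(7);
  out.names() = CharacterVector::create("score", "mismatches", "gaps",
                                        "q_start", "q_end",
                                        "s_start", "s_end");
  if (best <= 0) return out;

  int i = bi, j = bj, mismatches = 0, gapcols = 0;
  char state = 'H';
  int qs = bi, ss = bj;
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H[at(i, j)];
      if (h == 0) break;
      int s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      if (h == H[at(i - 1, j - 1)] + s) {
        if (s == mismatch) ++mismatches;
        qs = i; ss = j; --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {  // gap in query: subject base consumed
      ++gapcols;
      ss = j;
      if (E[at(i, j)] == H[at(i, j - 1)] + go) state = 'H';
      --j;
    } else {                    // gap in subject: query base consumed
      ++gapcols;
      qs = i;
      if (F[at(i, j)] == H[at(i - 1, j)] + go) state = 'H';
      --i;
    }
  }

  out["score"] = best;
  out["mismatches"] = mismatches;
  out["gaps"] = gapcols;
  out["q_start"] = qs;
  out["q_end"] = bi;
  out["s_start"] = ss;
  out["s_end"] = bj;
  return out;
}
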