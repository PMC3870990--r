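#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with linear gap penalty and full
// traceback. Returns the optimal local alignment's score, end-points on both
// sequences (1-based, inclusive), the number of identical aligned bases and
// the alignment column count. Deterministic tie-breaking: the best cell is
// the first one reached in row-major order with a strictly greater score;
// within a cell, diagonal moves are preferred over vertical over horizontal.
// [[Rcpp::export(name = ".smith_waterman_cpp")]]
List smith_waterman_cpp(std::string a, std::string b, int match, int mismatch,
                        int gap) {
  int n = (int) a.size(), m = (int) b.size();
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return (size_t) i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int diag = H[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      int up = H[idx(i - 1, j)] + gap;
      int left = H[idx(i, j - 1)] + gap;
      int v = diag;
      if (up > v) v = up;
      if (left > v) v = left;
      if (v < 0) v = 0;
      H[idx(i, j)] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0, _["matches"] = 0,
                        _["align_len"] = 0);
  }
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0 && H[idx(i, j)] > 0) {
    int h = H[idx(i, j)];
    int diag = H[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
    if (h == diag) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j; ++cols;
    } else if (h == H[idx(i - 1, j)] + gap) {
      --i; ++cols;
    } else {
      --j; ++cols;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["matches"] = matches, _["align_len"] = cols);
}

// End-anchored matching of a mature reference against a read: the mature
// sequence is slid across the read with a terminal offset of at most
// max_shift; bases falling outside the overlap on the mature side count
// against the shift budget, mismatches (including N) against the mismatch
// budget. Returns the minimum mismatch count over admissible shifts, or -1
// when no admissible placement exists.
// [[Rcpp::export(name = ".anchored_mismatch_cpp")]]
int anchored_mismatch_cpp(std::string read, std::string mature, int max_mismatch,
                          int max_shift) {
  int lr = (int) read.size(), lm = (int) mature.size();
  int best = -1;
  for (int s = -max_shift; s <= max_shift; ++s) {
    // mature position p (0-based) aligns to read position p + s
    int from = std::max(0, -s);           // first mature index inside read
    int to = std::min(lm, lr - s);        // one past last mature index inside
    if (to <= from) continue;
    int overhang = lm - (to - from);
    if (overhang > max_shift) continue;
    int mm = 0;
    for (int p = from; p < to; ++p) {
      char rb = read[p + s], mb = mature[p];
      if (rb != mb || rb == 'N') ++mm;
      if (mm > max_mismatch) break;
    }
    if (mm <= max_mismatch && (best < 0 || mm < best)) best = mm;
  }
  return best;
}
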