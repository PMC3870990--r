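#include <Rcpp.h>
#include <vector>
#include <stack>
#include <utility>
using namespace Rcpp;

// Pair score lookup on the RNA alphabet; non-canonical pairs are forbidden.
static inline int pair_score(char a, char b, int gc, int au, int gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return gu;
  return -1;
}

// Maximum-score nested secondary structure (Nussinov-style DP) with a
// configurable pair-scoring scheme and minimum hairpin loop length. The
// optimum is defined lexicographically: maximize total pair score, then the
// number of pairs (so equal-score structures with more pairs win), with a
// deterministic traceback that pairs a base rather than leaving it unpaired
// on full ties and picks the smallest admissible partner first.
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop, int score_gc, int score_au,
                  int score_gu) {
  int n = (int) seq.size();
  std::string db(n, '.');
  if (n < min_loop + 2) {
    return List::create(_["dot_bracket"] = db,
                        _["pairs_i"] = IntegerVector(0),
                        _["pairs_j"] = IntegerVector(0),
                        _["score"] = 0);
  }
  std::vector<int> S((size_t) n * n, 0), P((size_t) n * n, 0);
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int bs = S[idx(i + 1, j)], bp = P[idx(i + 1, j)];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int ps = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
        if (ps < 0) continue;
        bool has_inner = (k - i - 1 >= min_loop + 2);
        int is = has_inner ? S[idx(i + 1, k - 1)] : 0;
        int ip = has_inner ? P[idx(i + 1, k - 1)] : 0;
        int rs = (k < j) ? S[idx(k + 1, j)] : 0;
        int rp = (k < j) ? P[idx(k + 1, j)] : 0;
        int cs = ps + is + rs, cp = 1 + ip + rp;
        if (cs > bs || (cs == bs && cp > bp)) { bs = cs; bp = cp; }
      }
      S[idx(i, j)] = bs;
      P[idx(i, j)] = bp;
    }
  }

  // Traceback, iterative; prefer pairing i, smallest feasible partner first.
  std::vector<int> pi, pj;
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.top().first, j = todo.top().second;
    todo.pop();
    if (j - i < min_loop + 1) continue;
    int ts = S[idx(i, j)], tp = P[idx(i, j)];
    int chosen = -1;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      int ps = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
      if (ps < 0) continue;
      bool has_inner = (k - i - 1 >= min_loop + 2);
      int is = has_inner ? S[idx(i + 1, k - 1)] : 0;
      int ip = has_inner ? P[idx(i + 1, k - 1)] : 0;
      int rs = (k < j) ? S[idx(k + 1, j)] : 0;
      int rp = (k < j) ? P[idx(k + 1, j)] : 0;
      if (ps + is + rs == ts && 1 + ip + rp == tp) { chosen = k; break; }
    }
    if (chosen >= 0) {
      pi.push_back(i + 1);  // 1-based for R
      pj.push_back(chosen + 1);
      db[i] = '(';
      db[chosen] = ')';
      if (chosen - i - 1 >= min_loop + 2) todo.push(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) todo.push(std::make_pair(chosen + 1, j));
    } else {
      todo.push(std::make_pair(i + 1, j));
    }
  }

  return List::create(_["dot_bracket"] = db,
                      _["pairs_i"] = wrap(pi),
                      _["pairs_j"] = wrap(pj),
                      _["score"] = S[idx(0, n - 1)]);
}
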