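#include <Rcpp.h>
#include <string>
#include <vector>
#include <stack>

using namespace Rcpp;

// Pair weights: GC = 3, AU = 2, GU wobble = 1; T treated as U.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  bool aU = (a == 'U' || a == 'T');
  bool bU = (b == 'U' || b == 'T');
  if ((a == 'A' && bU) || (aU && b == 'A')) return 2;
  if ((a == 'G' && bU) || (aU && b == 'G')) return 1;
  return 0;
}

// Maximum-weight nested base-pairing (Nussinov-style) with a minimum
// hairpin loop. Returns the dot-bracket structure and the total score.
// Traceback is deterministic: at equal score, pairing beats leaving a
// base unpaired, and the most distal compatible partner is preferred,
// which favours long clean stems.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = (int) seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'U')
      stop("invalid character in sequence: '%c'", c);
  }
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["score"] = 0);

  // M[i][j] stored as flat vector, 0-based, j >= i.
  std::vector<int> M((size_t) n * n, 0);
  auto idx = [n](int i, int j) { return (size_t) i * n + j; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[idx(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int inner = M[idx(i + 1, k - 1)];
        int outer = (k + 1 <= j) ? M[idx(k + 1, j)] : 0;
        int cand = w + inner + outer;
        if (cand > best) best = cand;
      }
      M[idx(i, j)] = best;
    }
  }

  // Iterative traceback.
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    std::pair<int, int> ij = todo.top();
    todo.pop();
    int i = ij.first, j = ij.second;
    if (i >= j || j - i <= min_loop) continue;
    int target = M[idx(i, j)];
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int inner = M[idx(i + 1, k - 1)];
      int outer = (k + 1 <= j) ? M[idx(k + 1, j)] : 0;
      if (w + inner + outer == target) {
        db[i] = '(';
        db[k] = ')';
        todo.push(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) todo.push(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push(std::make_pair(i + 1, j));
  }

  return List::create(_["structure"] = db, _["score"] = M[idx(0, n - 1)]);
}
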