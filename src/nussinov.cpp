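#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Watson-Crick plus G:U, on codes A=1 C=2 G=3 U=4 (anything else unpairable)
static inline bool pairable(int a, int b) {
  if (a > b) std::swap(a, b);
  return (a == 1 && b == 4) || (a == 2 && b == 3) || (a == 3 && b == 4);
}

// Maximum base-pairing (Nussinov) with a minimum hairpin loop size.
// Returns the dot-bracket string, the pair count, and the partner vector
// (1-based, 0 = unpaired).
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector seq, int min_loop) {
  int n = seq.size();
  std::vector<std::vector<int> > N(n + 2, std::vector<int>(n + 2, 0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      int j = i + span;
      int best = N[i][j - 1];  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!pairable(seq[k - 1], seq[j - 1])) continue;
        int cand = 1 + N[k + 1][j - 1] + (k > i ? N[i][k - 1] : 0);
        if (cand > best) best = cand;
      }
      N[i][j] = best;
    }
  }

  IntegerVector partner(n, 0);
  std::string db(n, '.');
  // iterative traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(1, n));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (N[i][j] == N[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!pairable(seq[k - 1], seq[j - 1])) continue;
      int cand = 1 + N[k + 1][j - 1] + (k > i ? N[i][k - 1] : 0);
      if (cand == N[i][j]) {
        partner[k - 1] = j;
        partner[j - 1] = k;
        db[k - 1] = '(';
        db[j - 1] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  int npairs = N[1][n];
  return List::create(_["structure"] = db, _["npairs"] = npairs,
                      _["partner"] = partner);
}
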