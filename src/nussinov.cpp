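#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing secondary structure (Nussinov recurrence) with a
// minimum hairpin loop length. Returns the dot-bracket string of one
// optimal structure; ties are broken by leaving the 3' base unpaired,
// then pairing it with the 5'-most admissible partner.
// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::string db(n, '.');
  if (n == 0) return db;

  std::vector< std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[k], seq[j])) {
          int v = 1 + (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1];
          if (v > best) best = v;
        }
      }
      N[i][j] = best;
    }
  }

  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first;
    int j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (N[i][j] == N[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (can_pair(seq[k], seq[j])) {
        int v = 1 + (k > i ? N[i][k - 1] : 0) + N[k + 1][j - 1];
        if (v == N[i][j]) {
          db[k] = '(';
          db[j] = ')';
          if (k > i) stack.push_back(std::make_pair(i, k - 1));
          stack.push_back(std::make_pair(k + 1, j - 1));
          break;
        }
      }
    }
  }
  return db;
}
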