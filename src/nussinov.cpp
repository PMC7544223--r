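#include <Rcpp.h>
#include <string>
#include <vector>

// Watson-Crick + G.U wobble pairing on DNA-alphabet input (T acts as U)
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G') ||
         (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximal number of nested base pairs (Nussinov DP), hairpin loops of at
// least min_loop unpaired bases between any paired i, j.
// [[Rcpp::export]]
int nussinov_pairs_cpp(std::string seq, int min_loop) {
  const int n = (int)seq.size();
  if (n == 0) return 0;
  std::vector<int> dp((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return dp[(size_t)i * n + j]; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(i, j - 1); // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[(size_t)k], seq[(size_t)j])) {
          int left = (k > i) ? at(i, k - 1) : 0;
          int inside = at(k + 1, j - 1);
          int cand = left + inside + 1;
          if (cand > best) best = cand;
        }
      }
      at(i, j) = best;
    }
  }
  return at(0, n - 1);
}
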