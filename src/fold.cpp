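// Maximum base-pairing (Nussinov) fold used as an explicit, flagged
// approximation when no thermodynamic structure is supplied. Allowed pairs
// AU/GC/GU, minimum hairpin loop of 3 unpaired bases.
#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  auto code = [](char c) -> int {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
  };
  int x = code(a), y = code(b);
  if (x < 0 || y < 0) return false;
  if (x + y == 3) return true;                       // AU, CG
  return (x == 2 && y == 3) || (x == 3 && y == 2);   // GU
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop = 3) {
  const int n = (int)seq.size();
  std::vector<std::vector<int>> D(n + 1, std::vector<int>(n + 1, 0));
  // D[i][j] over 1-based inclusive interval, j - i > min_loop required to pair
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      int best = D[i][j - 1];                       // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) { // j pairs k
        if (can_pair(seq[k - 1], seq[j - 1])) {
          int v = 1 + D[k + 1][j - 1] + (k > i ? D[i][k - 1] : 0);
          if (v > best) best = v;
        }
      }
      D[i][j] = best;
    }
  }
  // traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  if (n > 0) stack.push_back({1, n});
  while (!stack.empty()) {
    auto [i, j] = stack.back(); stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (D[i][j] == D[i][j - 1]) { stack.push_back({i, j - 1}); continue; }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(seq[k - 1], seq[j - 1])) continue;
      int v = 1 + D[k + 1][j - 1] + (k > i ? D[i][k - 1] : 0);
      if (v == D[i][j]) {
        db[k - 1] = '('; db[j - 1] = ')';
        stack.push_back({k + 1, j - 1});
        if (k > i) stack.push_back({i, k - 1});
        break;
      }
    }
  }
  return List::create(_["pairs"] = (n > 0 ? D[1][n] : 0), _["dotbracket"] = db);
}
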