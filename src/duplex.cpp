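// Expectation-scored antiparallel duplex alignment between a small RNA and a
// target mRNA window (Allen-style penalties: mismatch 1, G:U wobble 0.5,
// affine gaps, seed-region penalties multiplied). Bounded to a small number
// of bulge (gap) events, which keeps plant miRNA duplexes realistic and the
// exhaustive test oracle tractable.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

// 0 = Watson-Crick pair, 1 = G:U wobble, 2 = mismatch.
// s = sRNA base, t = target base as written on the mRNA (sense) strand.
static inline int pair_class(int s, int t) {
  if (s < 0 || t < 0) return 2;
  if (s + t == 3) return 0;                      // A:T(U), C:G, G:C, T(U):A
  if ((s == 2 && t == 3) || (s == 3 && t == 2)) return 1; // G:U
  return 2;
}

struct Scheme {
  double mismatch, wobble, gap_open, gap_extend, seed_mult;
  int seed_start, seed_end;
  int max_bulges;
};

static inline double mult_at(const Scheme& sc, int i) {
  return (i >= sc.seed_start && i <= sc.seed_end) ? sc.seed_mult : 1.0;
}

// Global affine alignment of srna codes (length n, 5'->3') against the
// REVERSED target window codes (length m) so that sRNA position 1 faces the
// window's 3'-most base. States: M (aligned column), X (sRNA base bulged,
// gap in target), Y (target base bulged, gap in sRNA). Gap events <= max_bulges.
struct DPResult {
  double expectation;
  // traceback columns, 5'->3' of the sRNA
  std::vector<int> srna_pos;   // 0 where gap in sRNA
  std::vector<int> trev_pos;   // position in reversed window, 0 where gap
  std::vector<int> state;      // 0 pair, 1 wobble, 2 mismatch, 3 srna_bulge, 4 target_bulge
};

static DPResult duplex_dp(const std::vector<int>& s, const std::vector<int>& u,
                          const Scheme& sc, bool traceback) {
  const int n = (int)s.size(), m = (int)u.size(), B = sc.max_bulges + 1;
  auto idx = [&](int b, int i, int j) { return (b * (n + 1) + i) * (m + 1) + j; };
  std::vector<double> M(B * (n + 1) * (m + 1), INF), X = M, Y = M;
  // traceback codes: for M, predecessor state (0=M,1=X,2=Y); for X/Y, 0=open(M), 1=extend
  std::vector<signed char> tM, tX, tY;
  if (traceback) { tM.assign(M.size(), -1); tX = tM; tY = tM; }

  M[idx(0, 0, 0)] = 0.0;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i <= n; ++i) {
      for (int j = 0; j <= m; ++j) {
        if (i > 0 && j > 0) {
          int pc = pair_class(s[i - 1], u[j - 1]);
          double cost = (pc == 0) ? 0.0 : (pc == 1 ? sc.wobble : sc.mismatch) * mult_at(sc, i);
          double best = M[idx(b, i - 1, j - 1)]; int who = 0;
          if (X[idx(b, i - 1, j - 1)] < best) { best = X[idx(b, i - 1, j - 1)]; who = 1; }
          if (Y[idx(b, i - 1, j - 1)] < best) { best = Y[idx(b, i - 1, j - 1)]; who = 2; }
          if (best < INF) {
            M[idx(b, i, j)] = best + cost;
            if (traceback) tM[idx(b, i, j)] = (signed char)who;
          }
        }
        if (i > 0) {
          double mu = mult_at(sc, i);
          double open = (b > 0) ? M[idx(b - 1, i - 1, j)] + sc.gap_open * mu : INF;
          double ext = X[idx(b, i - 1, j)] + sc.gap_extend * mu;
          if (open <= ext) { X[idx(b, i, j)] = open; if (traceback) tX[idx(b, i, j)] = 0; }
          else             { X[idx(b, i, j)] = ext;  if (traceback) tX[idx(b, i, j)] = 1; }
        }
        if (j > 0) {
          int adj = (i < n) ? i + 1 : n;   // sRNA position adjacent to a target bulge
          double mu = mult_at(sc, adj);
          double open = (b > 0) ? M[idx(b - 1, i, j - 1)] + sc.gap_open * mu : INF;
          double ext = Y[idx(b, i, j - 1)] + sc.gap_extend * mu;
          if (open <= ext) { Y[idx(b, i, j)] = open; if (traceback) tY[idx(b, i, j)] = 0; }
          else             { Y[idx(b, i, j)] = ext;  if (traceback) tY[idx(b, i, j)] = 1; }
        }
      }
    }
  }

  DPResult res;
  res.expectation = INF;
  int bb = -1, st = -1;
  for (int b = 0; b < B; ++b) {
    if (M[idx(b, n, m)] < res.expectation) { res.expectation = M[idx(b, n, m)]; bb = b; st = 0; }
    if (X[idx(b, n, m)] < res.expectation) { res.expectation = X[idx(b, n, m)]; bb = b; st = 1; }
    if (Y[idx(b, n, m)] < res.expectation) { res.expectation = Y[idx(b, n, m)]; bb = b; st = 2; }
  }
  if (!traceback || !(res.expectation < INF)) return res;

  int i = n, j = m, b = bb, state = st;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int pc = pair_class(s[i - 1], u[j - 1]);
      res.srna_pos.push_back(i); res.trev_pos.push_back(j); res.state.push_back(pc);
      state = tM[idx(b, i, j)]; --i; --j;
    } else if (state == 1) {
      res.srna_pos.push_back(i); res.trev_pos.push_back(0); res.state.push_back(3);
      int mv = tX[idx(b, i, j)]; --i;
      if (mv == 0) { state = 0; --b; }
    } else {
      res.srna_pos.push_back(0); res.trev_pos.push_back(j); res.state.push_back(4);
      int mv = tY[idx(b, i, j)]; --j;
      if (mv == 0) { state = 0; --b; }
    }
  }
  std::reverse(res.srna_pos.begin(), res.srna_pos.end());
  std::reverse(res.trev_pos.begin(), res.trev_pos.end());
  std::reverse(res.state.begin(), res.state.end());
  return res;
}

static std::vector<int> encode(const std::string& x) {
  std::vector<int> v(x.size());
  for (size_t k = 0; k < x.size(); ++k) v[k] = base_code(x[k]);
  return v;
}

static Scheme make_scheme(List scheme) {
  Scheme sc;
  sc.mismatch = as<double>(scheme["mismatch_penalty"]);
  sc.wobble = as<double>(scheme["wobble_penalty"]);
  sc.gap_open = as<double>(scheme["gap_open_penalty"]);
  sc.gap_extend = as<double>(scheme["gap_extend_penalty"]);
  sc.seed_mult = as<double>(scheme["seed_multiplier"]);
  sc.seed_start = as<int>(scheme["seed_start"]);
  sc.seed_end = as<int>(scheme["seed_end"]);
  sc.max_bulges = as<int>(scheme["max_bulges"]);
  return sc;
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string srna, std::string window, List scheme) {
  Scheme sc = make_scheme(scheme);
  std::vector<int> s = encode(srna);
  std::string wrev(window.rbegin(), window.rend());
  std::vector<int> u = encode(wrev);
  DPResult r = duplex_dp(s, u, sc, true);
  int m = (int)u.size();
  IntegerVector srna_pos(r.srna_pos.size()), win_pos(r.srna_pos.size());
  IntegerVector state(r.state.size());
  for (size_t k = 0; k < r.srna_pos.size(); ++k) {
    srna_pos[k] = r.srna_pos[k] == 0 ? NA_INTEGER : r.srna_pos[k];
    // convert reversed-window index back to 1-based window coordinate
    win_pos[k] = r.trev_pos[k] == 0 ? NA_INTEGER : (m - r.trev_pos[k] + 1);
    state[k] = r.state[k];
  }
  return List::create(_["expectation"] = r.expectation,
                      _["srna_pos"] = srna_pos,
                      _["window_pos"] = win_pos,
                      _["state"] = state);
}

// Scan every window of the transcript whose length is within max_bulges of
// the sRNA length; return the minimum expectation per start and the end
// achieving it (ties broken toward the shorter window). One DP per window
// END covers all window lengths at once: the reversed window for a fixed end
// grows at the high-j side, so the optima for every length are the DP values
// in column j = length.
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
DataFrame duplex_scan_cpp(std::string srna, std::string transcript, List scheme) {
  Scheme sc = make_scheme(scheme);
  std::vector<int> s = encode(srna);
  const int n = (int)s.size(), L = (int)transcript.size();
  const int B = sc.max_bulges + 1;
  const int wmin = std::max(1, n - sc.max_bulges), wmax = n + sc.max_bulges;
  std::vector<double> bestExp(L + 1, INF);
  std::vector<int> bestEnd(L + 1, -1);
  // per-end DP, reusing flat arrays
  const int mcap = wmax;
  std::vector<double> M(B * (n + 1) * (mcap + 1)), X(M), Y(M);
  auto idx = [&](int b, int i, int j) { return (b * (n + 1) + i) * (mcap + 1) + j; };
  for (int end = wmin; end <= L; ++end) {
    int m = std::min(wmax, end);  // deepest usable window length at this end
    // u = reversed transcript[end-m+1 .. end]
    std::vector<int> u(m);
    for (int j = 0; j < m; ++j) u[j] = base_code(transcript[end - 1 - j]);
    std::fill(M.begin(), M.end(), INF);
    std::fill(X.begin(), X.end(), INF);
    std::fill(Y.begin(), Y.end(), INF);
    M[idx(0, 0, 0)] = 0.0;
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i <= n; ++i) {
        for (int j = 0; j <= m; ++j) {
          if (i > 0 && j > 0) {
            int pc = pair_class(s[i - 1], u[j - 1]);
            double cost = (pc == 0) ? 0.0 : (pc == 1 ? sc.wobble : sc.mismatch) * mult_at(sc, i);
            double v = std::min(M[idx(b, i - 1, j - 1)],
                       std::min(X[idx(b, i - 1, j - 1)], Y[idx(b, i - 1, j - 1)]));
            if (v < INF) M[idx(b, i, j)] = v + cost;
          }
          if (i > 0) {
            double mu = mult_at(sc, i);
            double open = (b > 0) ? M[idx(b - 1, i - 1, j)] + sc.gap_open * mu : INF;
            double ext = X[idx(b, i - 1, j)] + sc.gap_extend * mu;
            X[idx(b, i, j)] = std::min(open, ext);
          }
          if (j > 0) {
            int adj = (i < n) ? i + 1 : n;
            double mu = mult_at(sc, adj);
            double open = (b > 0) ? M[idx(b - 1, i, j - 1)] + sc.gap_open * mu : INF;
            double ext = Y[idx(b, i, j - 1)] + sc.gap_extend * mu;
            Y[idx(b, i, j)] = std::min(open, ext);
          }
        }
      }
    }
    for (int w = wmin; w <= std::min(m, wmax); ++w) {
      int start = end - w + 1;
      double e = INF;
      for (int b = 0; b < B; ++b) {
        e = std::min(e, std::min(M[idx(b, n, w)],
              std::min(X[idx(b, n, w)], Y[idx(b, n, w)])));
      }
      // per start keep min expectation; ties toward the smaller end
      if (e < bestExp[start] - 1e-12 ||
          (std::abs(e - bestExp[start]) <= 1e-12 && end < bestEnd[start])) {
        bestExp[start] = e; bestEnd[start] = end;
      }
    }
  }
  std::vector<int> starts, ends;
  std::vector<double> exps;
  for (int start = 1; start <= L; ++start) {
    if (bestEnd[start] > 0 && bestExp[start] < INF) {
      starts.push_back(start); ends.push_back(bestEnd[start]);
      exps.push_back(bestExp[start]);
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["expectation"] = exps);
}
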