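#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment.
// Scores: match > 0, mismatch < 0; a gap of length L costs open + L * ext
// (both positive), matching the pairwiseAlignment() convention.
// Returns best local score plus identity statistics from the traceback.
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              double match = 2.0, double mismatch = -3.0,
              double gap_open = 5.0, double gap_ext = 2.0) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["identity"] = 0.0,
                        _["align_length"] = 0, _["matches"] = 0);
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), 0.0);
  std::vector<double> F((n + 1) * (m + 1), 0.0);
  // traceback: 0 stop, 1 diag, 2 up (gap in b), 3 left (gap in a)
  std::vector<unsigned char> T((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  const double NEG = -1e30;
  for (int i = 0; i <= n; ++i) { E[i * (m + 1)] = NEG; F[i * (m + 1)] = NEG; }
  for (int j = 0; j <= m; ++j) { E[j] = NEG; F[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      int diag = (i - 1) * (m + 1) + (j - 1);
      double e = std::max(H[left] - gap_open - gap_ext, E[left] - gap_ext);
      double f = std::max(H[up] - gap_open - gap_ext, F[up] - gap_ext);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = H[diag] + s;
      double v = h; unsigned char t = 1;
      if (f > v) { v = f; t = 2; }
      if (e > v) { v = e; t = 3; }
      if (v <= 0.0) { v = 0.0; t = 0; }
      H[idx] = v; E[idx] = e; F[idx] = f; T[idx] = t;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // traceback from the best cell
  int i = bi, j = bj, alen = 0, nmatch = 0;
  while (i > 0 && j > 0) {
    unsigned char t = T[i * (m + 1) + j];
    if (t == 0) break;
    if (t == 1) {
      ++alen; if (a[i - 1] == b[j - 1]) ++nmatch;
      --i; --j;
    } else if (t == 2) { ++alen; --i; }
    else { ++alen; --j; }
  }
  double ident = alen > 0 ? 100.0 * nmatch / alen : 0.0;
  return List::create(_["score"] = best, _["identity"] = ident,
                      _["align_length"] = alen, _["matches"] = nmatch);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1; // N and anything else never pairs
  }
}

// Best contiguous-stack duplex between x and y (antiparallel), scanning every
// offset of x against reverse(y). pair_ok is a 16-entry 0/1 vector over
// x-base*4 + y-base; stackE is 16x16: energy of stacking pair p2 (at i+1)
// on pair p1 (at i), kcal/mol. Most negative contiguous segment wins.
// [[Rcpp::export(name = ".duplex_scan")]]
List duplex_scan(std::string x, std::string y,
                 IntegerVector pair_ok, NumericMatrix stackE) {
  int n = x.size(), m = y.size();
  std::vector<int> xc(n), yrc(m);
  for (int i = 0; i < n; ++i) xc[i] = base_code(x[i]);
  for (int j = 0; j < m; ++j) yrc[j] = base_code(y[m - 1 - j]); // reversed y
  double bestE = 0.0; int bestLen = 0;
  int best_xs = 0, best_xe = -1, best_js = 0, best_je = -1;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    // x[i] aligned with yrev[i - d]
    int i0 = std::max(0, d), i1 = std::min(n - 1, m - 1 + d);
    if (i1 - i0 < 1) continue; // need at least 2 aligned positions
    double cur = 0.0; int curStart = -1; // start index (pair) of current run
    bool prev_ok = false;
    int prev_pair = -1;
    for (int i = i0; i <= i1; ++i) {
      int j = i - d;
      int cxi = xc[i], cyj = yrc[j];
      bool ok = (cxi >= 0 && cyj >= 0 && pair_ok[cxi * 4 + cyj] != 0);
      int pair = ok ? cxi * 4 + cyj : -1;
      if (ok && prev_ok) {
        double e = stackE(prev_pair, pair);
        if (curStart < 0) { cur = e; curStart = i - 1; }
        else {
          if (cur + e <= e) { cur += e; }
          else { cur = e; curStart = i - 1; }
        }
        if (cur < bestE) {
          bestE = cur; bestLen = i - curStart + 1;
          best_xs = curStart; best_xe = i;
          best_js = curStart - d; best_je = i - d;
        }
      } else {
        cur = 0.0; curStart = -1;
      }
      prev_ok = ok; prev_pair = pair;
    }
  }
  if (best_xe < 0)
    return List::create(_["dG"] = 0.0, _["paired_length"] = 0,
                        _["x_start"] = NA_INTEGER, _["x_end"] = NA_INTEGER,
                        _["y_start"] = NA_INTEGER, _["y_end"] = NA_INTEGER);
  // convert reversed-y indices back to original y coordinates (1-based)
  int ys = m - best_je, ye = m - best_js;
  return List::create(_["dG"] = bestE, _["paired_length"] = bestLen,
                      _["x_start"] = best_xs + 1, _["x_end"] = best_xe + 1,
                      _["y_start"] = ys, _["y_end"] = ye);
}
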