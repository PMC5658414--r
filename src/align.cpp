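#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Best local alignment (Smith-Waterman, linear gap costs) with full column
// traceback, so callers can inspect gap placement (needed for
// trans-splicing error classification).  Local alignment leaves any
// combination of sequence ends unaligned, which is what fragment overlaps
// with unprocessed precursor flanks on either side require; callers apply
// their own dovetail/end-skip geometry checks to the reported core.
//
// An optional band restricts cells to |(j - (i - band_center))| <= band_width
// (i, j are 1-based prefix lengths of a and b; a_pos - b_pos ~ band_center on
// the anchor diagonal).  With a band covering the optimal path the result
// equals the unbanded optimum; callers seed the band from a shared k-mer.
// Banded runs use band-local storage, so memory and time are O(n * width).

static List traceback_and_result(const std::string &a, const std::string &b,
                                 int bi, int bj,
                                 const std::function<signed char(int, int)> &TB,
                                 double best) {
  std::vector<int> ai, bjv;
  int i = bi, j = bj;
  int matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    signed char d = TB(i, j);
    if (d == 0) break;
    if (d == 1) {
      ai.push_back(i); bjv.push_back(j);
      if (a[i - 1] == b[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (d == 2) {
      ai.push_back(i); bjv.push_back(0); ++cols; --i;
    } else {
      ai.push_back(0); bjv.push_back(j); ++cols; --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  IntegerVector a_idx(ai.size()), b_idx(bjv.size());
  for (size_t k = 0; k < ai.size(); ++k) {
    a_idx[k] = ai[k] == 0 ? NA_INTEGER : ai[k];
    b_idx[k] = bjv[k] == 0 ? NA_INTEGER : bjv[k];
  }
  return List::create(
    _["score"] = best,
    _["a_start"] = i + 1, _["a_end"] = bi,
    _["b_start"] = j + 1, _["b_end"] = bj,
    _["matches"] = matches, _["cols"] = cols,
    _["a_idx"] = a_idx, _["b_idx"] = b_idx);
}

// [[Rcpp::export]]
List olap_align_cpp(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap = -2.0,
                    int band_center = 0, int band_width = -1) {
  const int n = a.size(), m = b.size();

  if (band_width < 0) {
    // full matrix local alignment
    std::vector<double> S((size_t)(n + 1) * (m + 1), 0.0);
    std::vector<signed char> tb((size_t)(n + 1) * (m + 1), 0);
    auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
    double best = 0.0; int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        double sc = S[idx(i - 1, j - 1)] +
          (a[i - 1] == b[j - 1] ? match : mismatch);
        signed char dir = 1;
        double up = S[idx(i - 1, j)] + gap;
        if (up > sc) { sc = up; dir = 2; }
        double left = S[idx(i, j - 1)] + gap;
        if (left > sc) { sc = left; dir = 3; }
        if (sc <= 0.0) { continue; }    // restart (cell stays 0, tb 0)
        S[idx(i, j)] = sc; tb[idx(i, j)] = dir;
        if (sc > best) { best = sc; bi = i; bj = j; }
      }
    }
    auto TB = [&](int i, int j) { return tb[idx(i, j)]; };
    return traceback_and_result(a, b, bi, bj, TB, best);
  }

  // banded local alignment, band-local storage:
  // column c = j - (i - band_center) + W + 1
  const int W = band_width;
  const int width = 2 * W + 3;
  std::vector<double> S((size_t)(n + 1) * width, 0.0);
  std::vector<signed char> tb((size_t)(n + 1) * width, 0);
  auto cix = [&](int i, int j) { return (size_t)i * width + (j - (i - band_center) + W + 1); };
  auto inband = [&](int i, int j) {
    int c = j - (i - band_center) + W + 1;
    return c >= 1 && c <= 2 * W + 1;
  };
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - band_center - W);
    int jhi = std::min(m, i - band_center + W);
    for (int j = jlo; j <= jhi; ++j) {
      double sdiag = (i - 1 == 0 || j - 1 == 0) ? 0.0 :
        (inband(i - 1, j - 1) ? S[cix(i - 1, j - 1)] : 0.0);
      double sc = sdiag + (a[i - 1] == b[j - 1] ? match : mismatch);
      signed char dir = 1;
      double up = ((i - 1 == 0) ? 0.0 :
                   (inband(i - 1, j) ? S[cix(i - 1, j)] : 0.0)) + gap;
      if (up > sc) { sc = up; dir = 2; }
      double left = ((j - 1 == 0) ? 0.0 :
                     (inband(i, j - 1) ? S[cix(i, j - 1)] : 0.0)) + gap;
      if (left > sc) { sc = left; dir = 3; }
      if (sc <= 0.0) continue;
      S[cix(i, j)] = sc; tb[cix(i, j)] = dir;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  auto TB = [&](int i, int j) {
    if (i == 0 || j == 0 || !inband(i, j)) return (signed char)0;
    return tb[cix(i, j)];
  };
  return traceback_and_result(a, b, bi, bj, TB, best);
}
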