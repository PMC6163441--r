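#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Symmetric (edge-inclusive) reflection of an out-of-range index into [0, n).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Grayscale erosion/dilation with a Euclidean disk {(dr,dc): dr^2+dc^2 <= r^2}.
// The disk is decomposed into horizontal runs; each run is a sliding
// min/max (monotonic deque) over a reflect-padded row, so the cost is
// O(npix * (2r+1)) instead of O(npix * r^2).
// [[Rcpp::export]]
NumericMatrix cpp_gray_morph(NumericMatrix img, int radius, bool dilate) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  std::fill(out.begin(), out.end(), dilate ? R_NegInf : R_PosInf);
  std::vector<double> padded;
  std::vector<double> res(w);
  for (int dr = -radius; dr <= radius; ++dr) {
    const int wc = (int)std::floor(std::sqrt((double)radius * radius - (double)dr * dr));
    const int win = 2 * wc + 1;
    padded.assign(w + 2 * wc, 0.0);
    for (int i = 0; i < h; ++i) {
      const int sr = reflect_idx(i + dr, h);
      for (int k = -wc; k < w + wc; ++k)
        padded[k + wc] = img(sr, reflect_idx(k, w));
      std::deque<int> dq;
      for (int k = 0; k < w + 2 * wc; ++k) {
        const double v = padded[k];
        while (!dq.empty() &&
               (dilate ? padded[dq.back()] <= v : padded[dq.back()] >= v))
          dq.pop_back();
        dq.push_back(k);
        if (dq.front() <= k - win) dq.pop_front();
        if (k >= win - 1) res[k - win + 1] = padded[dq.front()];
      }
      for (int j = 0; j < w; ++j) {
        const double v = res[j];
        if (dilate) { if (v > out(i, j)) out(i, j) = v; }
        else        { if (v < out(i, j)) out(i, j) = v; }
      }
    }
  }
  return out;
}

// 8-connected labeling of nonzero pixels. Labels are assigned in row-major
// order of each component's first pixel (origin top-left), starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i * w + j);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pi = p / w, pj = p % w;
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            const int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= h || qj < 0 || qj >= w) continue;
            if (mask(qi, qj) != 0 && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi * w + qj);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Background flood fill from the image border, 4-connected (the complement
// of 8-connected foreground). Background regions not reached become
// foreground: the fixed point of reconstruction by erosion from a
// border-valued marker.
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(IntegerMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix reach(h, w);
  std::vector<int> stack;
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if ((i == 0 || i == h - 1 || j == 0 || j == w - 1) &&
          mask(i, j) == 0 && reach(i, j) == 0) {
        reach(i, j) = 1;
        stack.push_back(i * w + j);
        while (!stack.empty()) {
          const int p = stack.back(); stack.pop_back();
          const int pi = p / w, pj = p % w;
          const int ni[4] = {pi - 1, pi + 1, pi, pi};
          const int nj[4] = {pj, pj, pj - 1, pj + 1};
          for (int k = 0; k < 4; ++k) {
            const int qi = ni[k], qj = nj[k];
            if (qi < 0 || qi >= h || qj < 0 || qj >= w) continue;
            if (mask(qi, qj) == 0 && reach(qi, qj) == 0) {
              reach(qi, qj) = 1;
              stack.push_back(qi * w + qj);
            }
          }
        }
      }
    }
  }
  IntegerMatrix out(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      out(i, j) = (mask(i, j) != 0 || reach(i, j) == 0) ? 255 : 0;
  return out;
}
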