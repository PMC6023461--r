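#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// The structuring element is the disc of all (dr, dc) with
// dr^2 + dc^2 <= r^2; the non-flat "ball top" has height
// sqrt(r^2 - dr^2 - dc^2) there, a flat disc has height 0.

// Grayscale erosion/dilation with a disc-supported structuring element.
// Out-of-bounds neighbours are skipped (treated as +Inf for erosion and
// -Inf for dilation), so a constant image is a fixed point of the flat
// operators and maps to (c - r) / (c + r) under the ball-top ones.
// The accumulator is kept per output column and the innermost loop runs
// down contiguous column segments, which keeps the working set in cache
// and lets the compiler vectorise the min/max.
// [[Rcpp::export]]
NumericMatrix cpp_disc_morph(NumericMatrix img, double radius, bool dilate,
                             bool flat) {
  const int nr = img.nrow(), nc = img.ncol();
  const double r2 = radius * radius;
  const int amax = (int)std::floor(radius);
  NumericMatrix out(nr, nc);
  const double *x = img.begin();
  double *y = out.begin();
  std::vector<double> acc(nr);

  // chord extents and heights per |dc|
  std::vector<int> L(amax + 1);
  std::vector< std::vector<double> > H(amax + 1);
  for (int a = 0; a <= amax; ++a) {
    const double rem = r2 - (double)a * a;
    L[a] = (int)std::floor(std::sqrt(rem) + 1e-9);
    H[a].resize(2 * L[a] + 1);
    for (int dr = -L[a]; dr <= L[a]; ++dr)
      H[a][dr + L[a]] = flat ? 0.0
        : std::sqrt(rem - (double)dr * dr);
  }

  for (int c = 0; c < nc; ++c) {
    std::fill(acc.begin(), acc.end(), dilate ? R_NegInf : R_PosInf);
    for (int dc = -amax; dc <= amax; ++dc) {
      const int cc = c + dc;
      if (cc < 0 || cc >= nc) continue;
      const int a = dc < 0 ? -dc : dc;
      const double *src = x + (size_t)cc * nr;
      for (int dr = -L[a]; dr <= L[a]; ++dr) {
        const double h = H[a][dr + L[a]];
        const int r0 = dr < 0 ? -dr : 0;        // first valid output row
        const int r1 = dr > 0 ? nr - dr : nr;   // one past last valid row
        const double *s = src + dr;
        if (dilate) {
          for (int r = r0; r < r1; ++r) {
            const double t = s[r] + h;
            if (t > acc[r]) acc[r] = t;
          }
        } else {
          for (int r = r0; r < r1; ++r) {
            const double t = s[r] - h;
            if (t < acc[r]) acc[r] = t;
          }
        }
      }
    }
    std::copy(acc.begin(), acc.end(), y + (size_t)c * nr);
  }
  return out;
}

// Connected-component labelling by breadth-first flood fill in raster-scan
// (column-major) discovery order; labels are the contiguous set 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;

  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const size_t i = (size_t)c * nr + r;
      if (!mask[i] || lab[i]) continue;
      ++next;
      lab[i] = next;
      stack.push_back(r);
      stack.push_back(c);
      while (!stack.empty()) {
        const int cc0 = stack.back(); stack.pop_back();
        const int rr0 = stack.back(); stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int rr = rr0 + dr8[k], cc = cc0 + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          const size_t j = (size_t)cc * nr + rr;
          if (mask[j] && !lab[j]) {
            lab[j] = next;
            stack.push_back(rr);
            stack.push_back(cc);
          }
        }
      }
    }
  }
  return lab;
}

// Local mean over a (2w+1)x(2w+1) window with symmetric (edge-reflecting)
// padding, via a padded summed-area table.
// [[Rcpp::export]]
NumericMatrix cpp_local_mean(NumericMatrix img, int half) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = nr + 2 * half, pc = nc + 2 * half;
  std::vector<double> pad((size_t)pr * pc);
  for (int c = 0; c < pc; ++c) {
    int sc = c - half;
    if (sc < 0) sc = -sc - 1;
    if (sc >= nc) sc = 2 * nc - 1 - sc;
    for (int r = 0; r < pr; ++r) {
      int sr = r - half;
      if (sr < 0) sr = -sr - 1;
      if (sr >= nr) sr = 2 * nr - 1 - sr;
      pad[(size_t)c * pr + r] = img((size_t)sr, (size_t)sc);
    }
  }
  // summed-area table with a zero first row/column
  std::vector<double> sat((size_t)(pr + 1) * (pc + 1), 0.0);
  for (int c = 1; c <= pc; ++c)
    for (int r = 1; r <= pr; ++r)
      sat[(size_t)c * (pr + 1) + r] = pad[(size_t)(c - 1) * pr + (r - 1)] +
        sat[(size_t)(c - 1) * (pr + 1) + r] + sat[(size_t)c * (pr + 1) + r - 1] -
        sat[(size_t)(c - 1) * (pr + 1) + r - 1];
  NumericMatrix out(nr, nc);
  const double area = (double)(2 * half + 1) * (2 * half + 1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      const int r1 = r, r2 = r + 2 * half + 1;      // rows in padded sat
      const int c1 = c, c2 = c + 2 * half + 1;
      const double s = sat[(size_t)c2 * (pr + 1) + r2] -
        sat[(size_t)c1 * (pr + 1) + r2] - sat[(size_t)c2 * (pr + 1) + r1] +
        sat[(size_t)c1 * (pr + 1) + r1];
      out(r, c) = s / area;
    }
  return out;
}
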