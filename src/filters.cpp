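#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Windowed rank/mean filters with replicated borders. Windows are always full
// size (w x w): out-of-range indices clamp to the nearest edge, so the median
// of a window is taken over an odd count except in the (unreachable here)
// even case, defined as the mean of the two middle order statistics.

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

static double median_of(std::vector<double>& buf) {
  std::size_t n = buf.size();
  std::size_t mid = n / 2;
  std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
  double m = buf[mid];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + mid);
    m = (m + lo) / 2.0;
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((std::size_t)window * window);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int cj = clampi(j + dj, 0, nc - 1);
        for (int di = -h; di <= h; ++di)
          buf.push_back(img(clampi(i + di, 0, nr - 1), cj));
      }
      out(i, j) = median_of(buf);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix average_filter_cpp(NumericMatrix img, int window) {
  int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  double n = (double)window * window;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int dj = -h; dj <= h; ++dj) {
        int cj = clampi(j + dj, 0, nc - 1);
        for (int di = -h; di <= h; ++di)
          s += img(clampi(i + di, 0, nr - 1), cj);
      }
      out(i, j) = s / n;
    }
  }
  return out;
}

// Two-stage adaptive median. Stage A grows the window while its median is an
// extreme (== window min or max), up to smax; Stage B keeps the original
// pixel if it is not an extreme of the final window, else emits the median.
// [[Rcpp::export]]
NumericMatrix adaptive_median_filter_cpp(NumericMatrix img, int window, int smax) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((std::size_t)smax * smax);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int w = window;
      double zmed = 0, zmin = 0, zmax = 0;
      for (;;) {
        int h = w / 2;
        buf.clear();
        for (int dj = -h; dj <= h; ++dj) {
          int cj = clampi(j + dj, 0, nc - 1);
          for (int di = -h; di <= h; ++di)
            buf.push_back(img(clampi(i + di, 0, nr - 1), cj));
        }
        zmed = median_of(buf);
        zmin = *std::min_element(buf.begin(), buf.end());
        zmax = *std::max_element(buf.begin(), buf.end());
        if ((zmed > zmin && zmed < zmax) || w >= smax) break;
        w += 2;
      }
      double x = img(i, j);
      out(i, j) = (x > zmin && x < zmax) ? x : zmed;
    }
  }
  return out;
}

// 8-connected component labeling of a 0/1 mask; labels 1..n in scan order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          int cj = p.second + dj;
          if (cj < 0 || cj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int ci = p.first + di;
            if (ci < 0 || ci >= nr || (di == 0 && dj == 0)) continue;
            if (mask(ci, cj) != 0 && lab(ci, cj) == 0) {
              lab(ci, cj) = next;
              stack.push_back(std::make_pair(ci, cj));
            }
          }
        }
      }
    }
  }
  return lab;
}
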