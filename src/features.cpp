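#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Texture-statistic kernels used by the informativeness filter. Images are
// R matrices [row, col] with 8-bit values 0..255.

// Uniform local binary pattern code map, 8 neighbours at radius 1 (the
// classic 3x3 neighbourhood). A pattern is "uniform" when its circular
// 0/1 sequence has at most two transitions; uniform patterns are coded by
// their number of set bits (0..8), all others collapse to code 9. Border
// pixels (no full neighbourhood) keep code 0.
// [[Rcpp::export]]
IntegerMatrix lbp_code_map(const IntegerMatrix& img) {
  const int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w);
  // neighbour offsets, circular order
  const int dy[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const int dx[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  for (int y = 1; y < h - 1; ++y) {
    for (int x = 1; x < w - 1; ++x) {
      int c = img(y, x);
      int bits[8], ones = 0;
      for (int k = 0; k < 8; ++k) {
        bits[k] = img(y + dy[k], x + dx[k]) >= c ? 1 : 0;
        ones += bits[k];
      }
      int trans = 0;
      for (int k = 0; k < 8; ++k) trans += bits[k] != bits[(k + 1) % 8];
      out(y, x) = (trans <= 2) ? ones : 9;
    }
  }
  return out;
}

// Local Shannon entropy (bits) of the 8-bit histogram inside a disk of the
// given radius centred on each pixel; windows are clipped at the image
// border. Slides the disk along each row, maintaining the histogram and
// sum(n*log2(n)) incrementally: H = log2(N) - S/N.
// [[Rcpp::export]]
NumericMatrix local_entropy_map(const IntegerMatrix& img, int radius) {
  const int h = img.nrow(), w = img.ncol(), r = radius;
  if (r < 1) stop("local_entropy_map: radius must be >= 1");
  NumericMatrix out(h, w);
  // disk half-width per dy
  std::vector<int> ext(2 * r + 1);
  for (int dy = -r; dy <= r; ++dy)
    ext[dy + r] = (int)std::floor(std::sqrt((double)r * r - (double)dy * dy));
  // precompute n*log2(n)
  const int maxN = (2 * r + 1) * (2 * r + 1) + 1;
  std::vector<double> nlogn(maxN + 1, 0.0);
  for (int n = 2; n <= maxN; ++n) nlogn[n] = n * std::log2((double)n);

  std::vector<int> hist(256);
  for (int y = 0; y < h; ++y) {
    std::fill(hist.begin(), hist.end(), 0);
    double S = 0.0;
    int N = 0;
    // initialise window at x = 0
    for (int dy = -r; dy <= r; ++dy) {
      int yy = y + dy;
      if (yy < 0 || yy >= h) continue;
      int e = ext[dy + r];
      for (int xx = 0; xx <= e && xx < w; ++xx) {
        if (xx < -e) continue;
        int v = img(yy, xx);
        S += nlogn[hist[v] + 1] - nlogn[hist[v]];
        ++hist[v];
        ++N;
      }
    }
    out(y, 0) = N > 0 ? std::log2((double)N) - S / N : 0.0;
    for (int x = 1; x < w; ++x) {
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= h) continue;
        int e = ext[dy + r];
        int xout = x - 1 - e;  // leaves the window
        if (xout >= 0) {
          int v = img(yy, xout);
          S += nlogn[hist[v] - 1] - nlogn[hist[v]];
          --hist[v];
          --N;
        }
        int xin = x + e;  // enters the window
        if (xin < w) {
          int v = img(yy, xin);
          S += nlogn[hist[v] + 1] - nlogn[hist[v]];
          ++hist[v];
          ++N;
        }
      }
      out(y, x) = N > 0 ? std::log2((double)N) - S / N : 0.0;
    }
  }
  return out;
}

// Canny edge map on a pre-smoothed image: Sobel gradients (mirror
// boundary), 4-sector non-maximum suppression, double threshold at
// low_frac/high_frac of the maximum gradient magnitude, hysteresis by BFS
// from strong pixels through 8-connected weak pixels.
// [[Rcpp::export]]
IntegerMatrix canny_map(const NumericMatrix& smoothed,
                        double low_frac, double high_frac) {
  const int h = smoothed.nrow(), w = smoothed.ncol();
  IntegerMatrix out(h, w);
  if (h < 3 || w < 3) return out;
  NumericMatrix gx(h, w), gy(h, w), mag(h, w);
  auto at = [&](int y, int x) -> double {
    if (y < 0) y = -y; else if (y >= h) y = 2 * h - 2 - y;
    if (x < 0) x = -x; else if (x >= w) x = 2 * w - 2 - x;
    return smoothed(y, x);
  };
  double maxmag = 0.0;
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double sx = (at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y, x - 1) + at(y + 1, x - 1));
      double sy = (at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y - 1, x) + at(y - 1, x + 1));
      gx(y, x) = sx;
      gy(y, x) = sy;
      double m = std::sqrt(sx * sx + sy * sy);
      mag(y, x) = m;
      if (m > maxmag) maxmag = m;
    }
  }
  // guard against pure floating residue on flat images (0..255 scale)
  if (maxmag <= 1e-8) return out;
  const double low = low_frac * maxmag, high = high_frac * maxmag;
  // non-maximum suppression; 0 = weak-or-none, 1 = weak, 2 = strong
  IntegerMatrix cls(h, w);
  for (int y = 1; y < h - 1; ++y) {
    for (int x = 1; x < w - 1; ++x) {
      double m = mag(y, x);
      if (m < low) continue;
      double ang = std::atan2(gy(y, x), gx(y, x));
      if (ang < 0) ang += M_PI;
      double m1, m2;
      if (ang < M_PI / 8 || ang >= 7 * M_PI / 8) {          // horizontal grad
        m1 = mag(y, x - 1); m2 = mag(y, x + 1);
      } else if (ang < 3 * M_PI / 8) {                      // diagonal /
        m1 = mag(y - 1, x + 1); m2 = mag(y + 1, x - 1);
      } else if (ang < 5 * M_PI / 8) {                      // vertical grad
        m1 = mag(y - 1, x); m2 = mag(y + 1, x);
      } else {                                              // diagonal backslash
        m1 = mag(y - 1, x - 1); m2 = mag(y + 1, x + 1);
      }
      if (m >= m1 && m >= m2) cls(y, x) = (m >= high) ? 2 : 1;
    }
  }
  // hysteresis
  std::queue<std::pair<int, int> > q;
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (cls(y, x) == 2) { out(y, x) = 1; q.push(std::make_pair(y, x)); }
  while (!q.empty()) {
    int y = q.front().first, x = q.front().second;
    q.pop();
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        int yy = y + dy, xx = x + dx;
        if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
        if (cls(yy, xx) == 1 && out(yy, xx) == 0) {
          out(yy, xx) = 1;
          q.push(std::make_pair(yy, xx));
        }
      }
    }
  }
  return out;
}
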