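#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale opening with a spherical (ball) structuring element: the
// background an ideal ball of the given radius can reach when rolled
// underneath the intensity surface. Erosion then dilation with the
// non-flat kernel h(dy,dx) = sqrt(r^2 - dy^2 - dx^2).
// [[Rcpp::export]]
NumericMatrix ball_opening(NumericMatrix img, double radius) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> dy, dx;
  std::vector<double> h;
  for (int a = -r; a <= r; ++a) {
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        dy.push_back(a);
        dx.push_back(b);
        h.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
  const int K = (int)dy.size();
  NumericMatrix ero(H, W), out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double m = R_PosInf;
      for (int k = 0; k < K; ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = img(yy, xx) - h[k];
        if (v < m) m = v;
      }
      ero(y, x) = m;
    }
  }
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        int yy = y - dy[k], xx = x - dx[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = ero(yy, xx) + h[k];
        if (v > m) m = v;
      }
      out(y, x) = m;
    }
  }
  return out;
}
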