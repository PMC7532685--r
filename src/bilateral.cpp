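#include <Rcpp.h>
using namespace Rcpp;

// Bilateral filter with replicated borders: weights are the product of a
// spatial Gaussian (sigma_s, window truncated at 2 sigma_s) and a range
// Gaussian on intensity difference (sigma_r).
// [[Rcpp::export]]
NumericMatrix bilateral_cpp(NumericMatrix img, double sigma_s,
                            double sigma_r) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rad = (int) std::ceil(2.0 * sigma_s);
  const double s2 = 2.0 * sigma_s * sigma_s;
  const double r2 = 2.0 * sigma_r * sigma_r;
  NumericMatrix out(nr, nc);
  std::vector<double> ws((2 * rad + 1) * (2 * rad + 1));
  for (int dy = -rad; dy <= rad; ++dy)
    for (int dx = -rad; dx <= rad; ++dx)
      ws[(dy + rad) * (2 * rad + 1) + (dx + rad)] =
        std::exp(-(double)(dy * dy + dx * dx) / s2);
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      const double v0 = img(y, x);
      double num = 0.0, den = 0.0;
      for (int dy = -rad; dy <= rad; ++dy) {
        int yy = y + dy;
        if (yy < 0) yy = 0; else if (yy >= nr) yy = nr - 1;
        const int wrow = (dy + rad) * (2 * rad + 1);
        for (int dx = -rad; dx <= rad; ++dx) {
          int xx = x + dx;
          if (xx < 0) xx = 0; else if (xx >= nc) xx = nc - 1;
          const double v = img(yy, xx);
          const double w = ws[wrow + dx + rad] *
            std::exp(-(v - v0) * (v - v0) / r2);
          num += w * v;
          den += w;
        }
      }
      out(y, x) = num / den;
    }
  }
  return out;
}
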