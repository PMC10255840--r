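// Hampel sliding-window outlier filter and a small bilinear resampler.
// The Hampel rule: within the window [k-K, k+K] (truncated at the series
// boundaries) compute the median m_k and the scaled median absolute
// deviation S_k = 1.4826 * median(|x_j - m_k|); replace x_k by m_k when
// |x_k - m_k| > nth * S_k.  The filter is non-recursive: windows are drawn
// from the original series.  Medians follow R's convention (mean of the
// two central order statistics for even window lengths).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

const double MAD_SCALE = 1.4826;  // consistency factor for Gaussian noise

double median_of(std::vector<double>& buf) {
  std::sort(buf.begin(), buf.end());
  size_t n = buf.size();
  if (n % 2 == 1) return buf[n / 2];
  return 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
}

// filter a contiguous series of length n starting at x; writes to y and
// marks replacements; returns replacement count
int hampel_series(const double* x, int n, int K, double nth, double* y,
                  int* replaced) {
  int count = 0;
  std::vector<double> win, dev;
  for (int k = 0; k < n; ++k) {
    int lo = std::max(0, k - K), hi = std::min(n - 1, k + K);
    win.assign(x + lo, x + hi + 1);
    double m = median_of(win);
    dev.resize(win.size());
    for (size_t j = 0; j < win.size(); ++j) dev[j] = std::fabs(x[lo + (int)j] - m);
    double S = MAD_SCALE * median_of(dev);
    if (std::fabs(x[k] - m) > nth * S) {
      y[k] = m;
      if (replaced) replaced[k] = 1;
      ++count;
    } else {
      y[k] = x[k];
      if (replaced) replaced[k] = 0;
    }
  }
  return count;
}

}  // namespace

// [[Rcpp::export(name = ".hampel_vec")]]
List hampel_vec_cpp(NumericVector x, int K, double nth) {
  int n = x.size();
  NumericVector y(n);
  IntegerVector rep(n);
  int count = hampel_series(x.begin(), n, K, nth, y.begin(), rep.begin());
  return List::create(Named("values") = y, Named("replaced") = rep,
                      Named("n_replaced") = count);
}

// row-wise Hampel: each row of the map is one time series
// [[Rcpp::export(name = ".hampel_rows")]]
List hampel_rows_cpp(NumericMatrix m, int K, double nth) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> row(nc), filt(nc);
  int total = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = m(i, j);
    total += hampel_series(row.data(), nc, K, nth, filt.data(), nullptr);
    for (int j = 0; j < nc; ++j) out(i, j) = filt[j];
  }
  return List::create(Named("values") = out, Named("n_replaced") = total);
}

// bilinear resampling with pixel-centre alignment
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix m, int out_h, int out_w) {
  int H = m.nrow(), W = m.ncol();
  NumericMatrix out(out_h, out_w);
  for (int j = 0; j < out_w; ++j) {
    double sx = (j + 0.5) * W / out_w - 0.5;
    sx = std::max(0.0, std::min(sx, W - 1.0));
    int x0 = (int)std::floor(sx), x1 = std::min(x0 + 1, W - 1);
    double fx = sx - x0;
    for (int i = 0; i < out_h; ++i) {
      double sy = (i + 0.5) * H / out_h - 0.5;
      sy = std::max(0.0, std::min(sy, H - 1.0));
      int y0 = (int)std::floor(sy), y1 = std::min(y0 + 1, H - 1);
      double fy = sy - y0;
      out(i, j) = (1 - fy) * ((1 - fx) * m(y0, x0) + fx * m(y0, x1)) +
                  fy * ((1 - fx) * m(y1, x0) + fx * m(y1, x1));
    }
  }
  return out;
}
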