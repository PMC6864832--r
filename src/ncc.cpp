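#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zero-normalised cross-correlation scan of `templ` over a rectangular
// region of `frame`. Images are numeric matrices indexed [row, col], i.e.
// y (downward) first; x and y arguments are 0-based pixel coordinates and
// the region [x0, x1) x [y0, y1) is half-open. The returned matrix holds
// one score per candidate top-left anchor: row r, col c corresponds to
// anchor (x0 + c, y0 + r). Scores are clamped to [0, 1]; windows (or a
// template) with zero variance score 0.
//
// Window sums and sums of squares come from integral images over the
// region (O(1) per anchor); the cross term is the direct dot product
// with the mean-centred template.
// [[Rcpp::export]]
NumericMatrix ncc_scan_cpp(NumericMatrix frame, NumericMatrix templ,
                           int x0, int y0, int x1, int y1) {
  const int th = templ.nrow(), tw = templ.ncol();
  const int ny = (y1 - y0) - th + 1;
  const int nx = (x1 - x0) - tw + 1;
  if (ny < 1 || nx < 1)
    stop("template does not fit inside the search region");
  if (y1 > frame.nrow() || x1 > frame.ncol() || x0 < 0 || y0 < 0)
    stop("search region exceeds the frame");

  const double npix = static_cast<double>(tw) * static_cast<double>(th);
  double tmean = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += templ(i, j);
  tmean /= npix;

  std::vector<double> tc(static_cast<size_t>(tw) * th);
  double tss = 0.0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double v = templ(i, j) - tmean;
      tc[static_cast<size_t>(j) * th + i] = v;
      tss += v * v;
    }

  NumericMatrix out(ny, nx);
  if (tss <= 1e-24) return out;  // flat template: no signal anywhere

  // integral images of the region, padded with a zero row/column
  const int rh = y1 - y0, rw = x1 - x0;
  const int fn = frame.nrow();
  const double *f = REAL(frame);
  std::vector<double> S(static_cast<size_t>(rh + 1) * (rw + 1), 0.0);
  std::vector<double> Q(static_cast<size_t>(rh + 1) * (rw + 1), 0.0);
  const int sn = rh + 1;
  for (int c = 0; c < rw; ++c) {
    const double *col = f + static_cast<size_t>(x0 + c) * fn + y0;
    double runS = 0.0, runQ = 0.0;
    double *Sc = &S[static_cast<size_t>(c + 1) * sn];
    double *Qc = &Q[static_cast<size_t>(c + 1) * sn];
    const double *Sp = &S[static_cast<size_t>(c) * sn];
    const double *Qp = &Q[static_cast<size_t>(c) * sn];
    for (int r = 0; r < rh; ++r) {
      const double w = col[r];
      runS += w; runQ += w * w;
      Sc[r + 1] = Sp[r + 1] + runS;
      Qc[r + 1] = Qp[r + 1] + runQ;
    }
  }
  const size_t stride = sn;
  double *res = REAL(out);

  for (int ax = 0; ax < nx; ++ax) {
    const double *fcol0 = f + static_cast<size_t>(x0 + ax) * fn + y0;
    for (int ay = 0; ay < ny; ++ay) {
      double cross = 0.0;
      for (int j = 0; j < tw; ++j) {
        const double *w = fcol0 + static_cast<size_t>(j) * fn + ay;
        const double *t = &tc[static_cast<size_t>(j) * th];
        for (int i = 0; i < th; ++i) cross += w[i] * t[i];
      }
      const double *Sa = &S[static_cast<size_t>(ax) * stride + ay];
      const double *Qa = &Q[static_cast<size_t>(ax) * stride + ay];
      const double ws = Sa[static_cast<size_t>(tw) * stride + th] -
                        Sa[static_cast<size_t>(tw) * stride] - Sa[th] + Sa[0];
      const double wss = Qa[static_cast<size_t>(tw) * stride + th] -
                         Qa[static_cast<size_t>(tw) * stride] - Qa[th] + Qa[0];
      const double wvar = wss - ws * ws / npix;
      const double denom = std::sqrt(wvar * tss);
      double s = (denom > 1e-12) ? cross / denom : 0.0;
      if (s < 0.0) s = 0.0;
      if (s > 1.0) s = 1.0;
      res[static_cast<size_t>(ax) * ny + ay] = s;
    }
  }
  return out;
}
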