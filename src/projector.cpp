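#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of an n x n image (column-major, first index = x).
// Coordinates in pixel units relative to the image center.
static inline double sample_bilinear(const double *img, int n,
                                     double xpix, double ypix) {
  double cx = xpix + (n - 1) / 2.0;
  double cy = ypix + (n - 1) / 2.0;
  int ix = (int)std::floor(cx), iy = (int)std::floor(cy);
  if (ix < 0 || iy < 0 || ix >= n - 1 || iy >= n - 1) return 0.0;
  double fx = cx - ix, fy = cy - iy;
  const double *col0 = img + (size_t)iy * n;
  const double *col1 = col0 + n;
  double v00 = col0[ix], v10 = col0[ix + 1];
  double v01 = col1[ix], v11 = col1[ix + 1];
  return (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11;
}

// Parallel-beam forward projection by ray sampling.
// image: n x n raster; pixel_mm: spacing; angles: radians; det_pos_mm:
// detector channel offsets from isocenter. Returns line integrals in
// (raster unit) * mm, as an n_det x n_angles matrix.
// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericMatrix image, double pixel_mm,
                                  NumericVector angles,
                                  NumericVector det_pos_mm,
                                  double step_frac = 0.5) {
  int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  int n_ang = angles.size(), n_det = det_pos_mm.size();
  NumericMatrix sino(n_det, n_ang);
  double half_diag = 0.5 * n * pixel_mm * M_SQRT2;
  double step = pixel_mm * step_frac;
  int n_step = (int)std::ceil(2.0 * half_diag / step) + 1;
  const double *img = REAL(image);
  for (int a = 0; a < n_ang; ++a) {
    double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int d = 0; d < n_det; ++d) {
      double sx = det_pos_mm[d] * c, sy = det_pos_mm[d] * s;
      double acc = 0.0;
      double t0 = -half_diag;
      for (int k = 0; k < n_step; ++k) {
        double t = t0 + k * step;
        double x = (sx - t * s) / pixel_mm;
        double y = (sy + t * c) / pixel_mm;
        acc += sample_bilinear(img, n, x, y);
      }
      sino(d, a) = acc * step;
    }
  }
  return sino;
}

// Backprojection of a filtered sinogram onto an n x n grid, scaled by
// pi / n_angles (the standard FBP angular quadrature weight).
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix fsino, NumericVector angles,
                              NumericVector det_pos_mm, int n,
                              double pixel_mm) {
  int n_ang = angles.size(), n_det = fsino.nrow();
  if (fsino.ncol() != n_ang) stop("sinogram/angle mismatch");
  double d0 = det_pos_mm[0];
  double dd = (det_pos_mm[n_det - 1] - d0) / (n_det - 1);
  NumericMatrix out(n, n);
  double *o = REAL(out);
  const double *f = REAL(fsino);
  std::vector<double> cs(n_ang), sn(n_ang);
  for (int a = 0; a < n_ang; ++a) {
    cs[a] = std::cos(angles[a]);
    sn[a] = std::sin(angles[a]);
  }
  double scale = M_PI / n_ang;
  for (int iy = 0; iy < n; ++iy) {
    double y = (iy - (n - 1) / 2.0) * pixel_mm;
    for (int ix = 0; ix < n; ++ix) {
      double x = (ix - (n - 1) / 2.0) * pixel_mm;
      double acc = 0.0;
      for (int a = 0; a < n_ang; ++a) {
        double spos = (x * cs[a] + y * sn[a] - d0) / dd;
        int k = (int)std::floor(spos);
        if (k < 0 || k >= n_det - 1) continue;
        double fr = spos - k;
        const double *col = f + (size_t)a * n_det;
        acc += (1 - fr) * col[k] + fr * col[k + 1];
      }
      o[(size_t)iy * n + ix] = acc * scale;
    }
  }
  return out;
}
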