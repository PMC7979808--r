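#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expected photon counts per pixel from Gaussian emitters, integrated over
// the pixel grid with periodic boundary wrapping.
//
// xs, ys   : T x M matrices of emitter positions (um), origin at the top-left
//            corner of pixel (0,0); x runs along columns, y along rows.
// amp      : T x M matrix of emitter amplitudes (expected counts/frame;
//            0 = dark or bleached).
// H, W     : image size in pixels.
// a_um     : object-plane pixel size (um).
// sigma_um : Gaussian PSF standard deviation (um) = (1/e^2 radius) / 2.
//
// Returns a H x W x T array of expected counts.
// [[Rcpp::export]]
NumericVector deposit_frames_cpp(const NumericMatrix& xs,
                                 const NumericMatrix& ys,
                                 const NumericMatrix& amp,
                                 int H, int W, double a_um, double sigma_um) {
  const int T = xs.nrow(), M = xs.ncol();
  NumericVector out(Dimension(H, W, T));
  const double s2 = sigma_um * std::sqrt(2.0);
  const int win = (int)std::ceil(4.0 * sigma_um / a_um) + 1;
  std::vector<double> ex(2 * win + 2), ey(2 * win + 2);
  const double Lx = W * a_um, Ly = H * a_um;
  for (int t = 0; t < T; ++t) {
    double* frame = &out[(size_t)t * H * W];
    for (int m = 0; m < M; ++m) {
      const double A = amp(t, m);
      if (A <= 0) continue;
      double x = xs(t, m); x -= Lx * std::floor(x / Lx);
      double y = ys(t, m); y -= Ly * std::floor(y / Ly);
      const int jc = (int)std::floor(x / a_um);
      const int ic = (int)std::floor(y / a_um);
      // erf at pixel boundaries jc-win .. jc+win+1 (unwrapped coordinates)
      const int nb = 2 * win + 2;
      for (int k = 0; k < nb; ++k) {
        ex[k] = std::erf(((jc - win + k) * a_um - x) / s2);
        ey[k] = std::erf(((ic - win + k) * a_um - y) / s2);
      }
      for (int di = -win; di <= win; ++di) {
        int i = ic + di;
        i %= H; if (i < 0) i += H;
        const double fy = 0.5 * (ey[di + win + 1] - ey[di + win]);
        for (int dj = -win; dj <= win; ++dj) {
          int j = jc + dj;
          j %= W; if (j < 0) j += W;
          const double fx = 0.5 * (ex[dj + win + 1] - ex[dj + win]);
          frame[j * H + i] += A * fx * fy;
        }
      }
    }
  }
  return out;
}

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

// Catmull-Rom bicubic interpolation of matrix img at (x, y) in 0-based pixel
// coordinates (x along columns, y along rows); clamped at the borders.
static double interp_bicubic(const NumericMatrix& img, double x, double y) {
  const int H = img.nrow(), W = img.ncol();
  int j0 = (int)std::floor(x), i0 = (int)std::floor(y);
  double tx = x - j0, ty = y - i0;
  double col[4];
  for (int a = -1; a <= 2; ++a) {
    int i = i0 + a; if (i < 0) i = 0; if (i >= H) i = H - 1;
    double row[4];
    for (int b = -1; b <= 2; ++b) {
      int j = j0 + b; if (j < 0) j = 0; if (j >= W) j = W - 1;
      row[b + 1] = img(i, j);
    }
    col[a + 1] = catmull_rom(row[0], row[1], row[2], row[3], tx);
  }
  return catmull_rom(col[0], col[1], col[2], col[3], ty);
}

// Radiality transform of one frame on an M-times finer sub-pixel grid.
//
// For each sub-pixel centre c, 2*axes points are sampled on a ring of radius
// ring_radius (original pixels) around c. At each sample the intensity
// gradient (central differences, bicubically interpolated) defines a line
// through the sample; its perpendicular distance d from c scores the sample
// as sign(convergence) * max(0, 1 - d/ring_radius), where the sign is + when
// the gradient points toward c (intensity decaying away from c). The
// radiality is the sample mean, clipped below at 0, optionally multiplied by
// the interpolated intensity at c.
// [[Rcpp::export]]
NumericMatrix radiality_cpp(const NumericMatrix& frame, int M,
                            double ring_radius, int axes, bool weighted) {
  const int H = frame.nrow(), W = frame.ncol();
  NumericMatrix gx(H, W), gy(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int jm = j > 0 ? j - 1 : 0, jp = j < W - 1 ? j + 1 : W - 1;
      int im = i > 0 ? i - 1 : 0, ip = i < H - 1 ? i + 1 : H - 1;
      gx(i, j) = 0.5 * (frame(i, jp) - frame(i, jm));
      gy(i, j) = 0.5 * (frame(ip, j) - frame(im, j));
    }
  const int ns = 2 * axes;
  std::vector<double> cs(ns), sn(ns);
  for (int k = 0; k < ns; ++k) {
    double th = M_PI * (2.0 * k + 1.0) / ns;   // offset to avoid axis lock
    cs[k] = std::cos(th); sn[k] = std::sin(th);
  }
  NumericMatrix out(M * H, M * W);
  for (int si = 0; si < M * H; ++si) {
    double cy = (si + 0.5) / M - 0.5;
    for (int sj = 0; sj < M * W; ++sj) {
      double cx = (sj + 0.5) / M - 0.5;
      double acc = 0.0;
      for (int k = 0; k < ns; ++k) {
        double pxs = cx + ring_radius * cs[k];
        double pys = cy + ring_radius * sn[k];
        double g1 = interp_bicubic(gx, pxs, pys);
        double g2 = interp_bicubic(gy, pxs, pys);
        double gn = std::sqrt(g1 * g1 + g2 * g2);
        if (gn < 1e-12) continue;                  // flat: no contribution
        // perpendicular distance of the gradient line from c
        double dx = pxs - cx, dy = pys - cy;
        double d = std::fabs(dx * g2 - dy * g1) / gn;
        double score = 1.0 - d / ring_radius;
        if (score < 0) score = 0;
        double conv = -(dx * g1 + dy * g2);        // >0: gradient toward c
        acc += (conv > 0 ? score : -score);
      }
      double r = acc / ns;
      if (r < 0) r = 0;
      if (weighted) {
        double w = interp_bicubic(frame, cx, cy);
        if (w < 0) w = 0;
        r *= w;
      }
      out(si, sj) = r;
    }
  }
  return out;
}
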