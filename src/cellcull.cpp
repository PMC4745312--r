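#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Grayscale morphological reconstruction by dilation (8-connectivity),
// hybrid raster/FIFO algorithm. marker <= mask is required; the result is
// the largest image <= mask whose regional maxima are seeded by marker.
// [[Rcpp::export]]
NumericMatrix recon_dilate_cpp(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(clone(marker));
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) stop("marker must be <= mask everywhere");

  // neighbour offsets split into raster-order (N+) and anti-raster (N-)
  const int dr_plus[4]  = {-1, -1, -1,  0};
  const int dc_plus[4]  = {-1,  0,  1, -1};
  const int dr_minus[4] = { 1,  1,  1,  0};
  const int dc_minus[4] = {-1,  0,  1,  1};

  // forward raster sweep (row-major, matching the N+ neighbour set)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_plus[k], cc = c + dc_plus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
    }

  // backward sweep, queueing pixels that can still propagate
  std::queue<std::pair<int, int> > fifo;
  for (int r = nr - 1; r >= 0; --r)
    for (int c = nc - 1; c >= 0; --c) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_minus[k], cc = c + dc_minus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr_minus[k], cc = c + dc_minus[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(std::make_pair(r, c));
          break;
        }
      }
    }

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        fifo.push(std::make_pair(rr, cc));
      }
    }
  }
  return J;
}

static inline double cubic_kernel(double x) {
  // Catmull-Rom (a = -0.5), the conventional bicubic interpolation kernel
  const double a = -0.5;
  x = std::fabs(x);
  if (x <= 1.0) return ((a + 2.0) * x - (a + 3.0)) * x * x + 1.0;
  if (x < 2.0)  return (((x - 5.0) * x + 8.0) * x - 4.0) * a;
  return 0.0;
}

// Bicubic resampling with centre-aligned pixel mapping and edge clamping.
// [[Rcpp::export]]
NumericMatrix resize_bicubic_cpp(NumericMatrix img, int out_h, int out_w) {
  int nr = img.nrow(), nc = img.ncol();
  if (nr < 2 || nc < 2) stop("image too small to resample");
  if (out_h < 1 || out_w < 1) stop("output dimensions must be positive");
  double sr = (double)nr / out_h, sc = (double)nc / out_w;
  NumericMatrix out(out_h, out_w);

  // separable pass: rows then columns
  NumericMatrix tmp(out_h, nc);
  for (int r = 0; r < out_h; ++r) {
    double y = (r + 0.5) * sr - 0.5;
    int y0 = (int)std::floor(y);
    double wy[4];
    for (int k = 0; k < 4; ++k) wy[k] = cubic_kernel(y - (y0 - 1 + k));
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0, wsum = 0.0;
      for (int k = 0; k < 4; ++k) {
        int rr = y0 - 1 + k;
        if (rr < 0) rr = 0;
        if (rr >= nr) rr = nr - 1;
        acc += wy[k] * img(rr, c);
        wsum += wy[k];
      }
      tmp(r, c) = acc / wsum;
    }
  }
  for (int c = 0; c < out_w; ++c) {
    double x = (c + 0.5) * sc - 0.5;
    int x0 = (int)std::floor(x);
    double wx[4];
    for (int k = 0; k < 4; ++k) wx[k] = cubic_kernel(x - (x0 - 1 + k));
    for (int r = 0; r < out_h; ++r) {
      double acc = 0.0, wsum = 0.0;
      for (int k = 0; k < 4; ++k) {
        int cc = x0 - 1 + k;
        if (cc < 0) cc = 0;
        if (cc >= nc) cc = nc - 1;
        acc += wx[k] * tmp(r, cc);
        wsum += wx[k];
      }
      out(r, c) = acc / wsum;
    }
  }
  return out;
}

// Moore-neighbour boundary trace of a single connected component, clockwise
// from the topmost-leftmost foreground pixel. Returns 1-based (row, col).
// [[Rcpp::export]]
IntegerMatrix trace_boundary_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty mask");

  // clockwise Moore neighbourhood, starting W, in image coordinates
  const int dr8[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> rows, cols;
  int r = sr, c = sc;
  int dir = 0; // backtrack direction: came from W
  rows.push_back(r); cols.push_back(c);
  int guard = 0, maxsteps = 4 * (nr * nc + 4);
  while (guard++ < maxsteps) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int d = (dir + 1 + k) % 8; // start just after backtrack, clockwise
      int rr = r + dr8[d], cc = c + dc8[d];
      if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && mask(rr, cc)) {
        found = d;
        r = rr; c = cc;
        break;
      }
    }
    if (found < 0) break; // isolated pixel
    if (r == sr && c == sc) break;
    rows.push_back(r); cols.push_back(c);
    dir = (found + 4) % 8; // new backtrack = reverse of move
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}
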