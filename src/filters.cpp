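#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Images are plain numeric matrices, column-major as R stores them:
// img(row, col) = img[y, x], y growing downward.

static std::vector<double> gauss_kernel(double sigma) {
  int radius = (int)std::ceil(3.5 * sigma);
  if (radius < 1) radius = 1;
  std::vector<double> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    double v = std::exp(-(double)(i * i) / s2);
    k[i + radius] = v;
    sum += v;
  }
  for (double &v : k) v /= sum;
  return k;
}

// Separable Gaussian blur with replicate (clamp-to-edge) padding.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(const NumericMatrix &img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> k = gauss_kernel(sigma);
  int radius = ((int)k.size() - 1) / 2;

  // 1-D convolution of a contiguous line with replicate padding,
  // branch-free in the interior for speed
  std::vector<double> pad, line;
  NumericMatrix tmp(h, w), out(h, w);

  // vertical pass: columns are contiguous in R's column-major layout
  pad.resize(h + 2 * radius);
  for (int x = 0; x < w; ++x) {
    const double *col = &img(0, x);
    for (int t = 0; t < radius; ++t) pad[t] = col[0];
    for (int y = 0; y < h; ++y) pad[radius + y] = col[y];
    for (int t = 0; t < radius; ++t) pad[radius + h + t] = col[h - 1];
    double *dst = &tmp(0, x);
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      const double *src = &pad[y];
      for (int t = 0; t <= 2 * radius; ++t) acc += k[t] * src[t];
      dst[y] = acc;
    }
  }
  // horizontal pass: gather each row into a contiguous buffer once
  pad.resize(w + 2 * radius);
  line.resize(w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) pad[radius + x] = tmp(y, x);
    for (int t = 0; t < radius; ++t) pad[t] = pad[radius];
    for (int t = 0; t < radius; ++t) pad[radius + w + t] = pad[radius + w - 1];
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      const double *src = &pad[x];
      for (int t = 0; t <= 2 * radius; ++t) acc += k[t] * src[t];
      line[x] = acc;
    }
    for (int x = 0; x < w; ++x) out(y, x) = line[x];
  }
  return out;
}

// Area-average (box-integration) resampling; exact for constant images and
// antialiased for arbitrary downscale factors.
// [[Rcpp::export]]
NumericMatrix resize_area_cpp(const NumericMatrix &img, int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  if (out_h <= 0 || out_w <= 0) stop("output dimensions must be positive");
  double sy = (double)h / out_h, sx = (double)w / out_w;
  NumericMatrix out(out_h, out_w);
  for (int oy = 0; oy < out_h; ++oy) {
    double y0 = oy * sy, y1 = (oy + 1) * sy;
    int iy0 = (int)std::floor(y0), iy1 = (int)std::ceil(y1);
    if (iy1 > h) iy1 = h;
    for (int ox = 0; ox < out_w; ++ox) {
      double x0 = ox * sx, x1 = (ox + 1) * sx;
      int ix0 = (int)std::floor(x0), ix1 = (int)std::ceil(x1);
      if (ix1 > w) ix1 = w;
      double acc = 0.0, area = 0.0;
      for (int iy = iy0; iy < iy1; ++iy) {
        double wy = std::min((double)iy + 1.0, y1) - std::max((double)iy, y0);
        for (int ix = ix0; ix < ix1; ++ix) {
          double wx = std::min((double)ix + 1.0, x1) - std::max((double)ix, x0);
          acc += wy * wx * img(iy, ix);
          area += wy * wx;
        }
      }
      out(oy, ox) = acc / area;
    }
  }
  return out;
}

// Bilinear resampling with half-pixel center alignment.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(const NumericMatrix &img, int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  if (out_h <= 0 || out_w <= 0) stop("output dimensions must be positive");
  double sy = (double)h / out_h, sx = (double)w / out_w;
  NumericMatrix out(out_h, out_w);
  for (int oy = 0; oy < out_h; ++oy) {
    double fy = (oy + 0.5) * sy - 0.5;
    if (fy < 0) fy = 0; if (fy > h - 1) fy = h - 1;
    int y0 = (int)std::floor(fy);
    int y1 = std::min(y0 + 1, h - 1);
    double wy = fy - y0;
    for (int ox = 0; ox < out_w; ++ox) {
      double fx = (ox + 0.5) * sx - 0.5;
      if (fx < 0) fx = 0; if (fx > w - 1) fx = w - 1;
      int x0 = (int)std::floor(fx);
      int x1 = std::min(x0 + 1, w - 1);
      double wx = fx - x0;
      out(oy, ox) = (1 - wy) * ((1 - wx) * img(y0, x0) + wx * img(y0, x1)) +
                    wy * ((1 - wx) * img(y1, x0) + wx * img(y1, x1));
    }
  }
  return out;
}

// 4-connected component labelling (BFS); labels 1..n, background 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix &mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  const int dy[4] = {-1, 1, 0, 0}, dx[4] = {0, 0, -1, 1};
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      lab(y, x) = ++next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int d = 0; d < 4; ++d) {
          int ny = p.first + dy[d], nx = p.second + dx[d];
          if (ny < 0 || ny >= h || nx < 0 || nx >= w) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            q.push(std::make_pair(ny, nx));
          }
        }
      }
    }
  }
  return lab;
}

// Strict local maxima of a scale-space stack (list of equally sized
// matrices) over the 3x3x3 neighbourhood, value > threshold.  Border
// layers have no scale neighbour on one side and are excluded, matching
// the padded-ladder construction in the R caller; spatial borders are
// allowed (the neighbourhood is clamped to the image) so that a
// structure cut by a tile seam still peaks in the tiles that see it.
// Returns a matrix with columns (row, col, layer, value), 1-based.
// [[Rcpp::export]]
NumericMatrix local_maxima3d_cpp(const List &stack, double threshold) {
  int n = stack.size();
  if (n < 3) return NumericMatrix(0, 4);
  std::vector<NumericMatrix> L(n);
  for (int i = 0; i < n; ++i) L[i] = as<NumericMatrix>(stack[i]);
  int h = L[0].nrow(), w = L[0].ncol();
  std::vector<double> rows, cols, lays, vals;
  for (int k = 1; k < n - 1; ++k) {
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        double v = L[k](y, x);
        if (v <= threshold) continue;
        bool ismax = true;
        for (int dk = -1; dk <= 1 && ismax; ++dk)
          for (int dx = -1; dx <= 1 && ismax; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= w) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int yy = y + dy;
              if (yy < 0 || yy >= h) continue;
              if (dk == 0 && dx == 0 && dy == 0) continue;
              if (L[k + dk](yy, xx) >= v) { ismax = false; break; }
            }
          }
        if (ismax) {
          rows.push_back(y + 1);
          cols.push_back(x + 1);
          lays.push_back(k + 1);
          vals.push_back(v);
        }
      }
    }
  }
  NumericMatrix out(rows.size(), 4);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i]; out(i, 1) = cols[i];
    out(i, 2) = lays[i]; out(i, 3) = vals[i];
  }
  colnames(out) = CharacterVector::create("row", "col", "layer", "value");
  return out;
}
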