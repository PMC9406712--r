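// Low-level numeric kernels: bilinear resampling, straight-ray projection of a
// volume, quality-guided phase unwrapping, 3D connected components, separable
// convolution. All coordinates are 0-based internally; R wrappers pass centers
// in 1-based matrix coordinates and convert.
#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <cmath>
using namespace Rcpp;

static inline double bilin(const double* img, int nr, int nc,
                           double r, double c, double fill) {
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return fill;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = r - r0, fc = c - c0;
  double v00 = img[r0 + nr * c0], v10 = img[r1 + nr * c0];
  double v01 = img[r0 + nr * c1], v11 = img[r1 + nr * c1];
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11);
}

// Rotate a matrix by angle (degrees) about center (cr, cc) (0-based row/col).
// out(r,c) = img at R(-a) * (dst - ctr) + ctr; positive angle rotates the image
// content so that a feature at +row moves toward +col (consistent with the
// projector convention below).
// [[Rcpp::export(name = ".rotate_bilinear_cpp")]]
NumericMatrix rotate_bilinear_cpp(NumericMatrix img, double angle_deg,
                                  double cr, double cc, double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  const double* p = img.begin();
  for (int c = 0; c < nc; ++c) {
    double dc = c - cc;
    for (int r = 0; r < nr; ++r) {
      double dr = r - cr;
      double sr = ca * dr + sa * dc + cr;
      double sc = -sa * dr + ca * dc + cc;
      out(r, c) = bilin(p, nr, nc, sr, sc, fill);
    }
  }
  return out;
}

// Translate a matrix by (drow, dcol) pixels, bilinear, fill outside.
// [[Rcpp::export(name = ".shift_bilinear_cpp")]]
NumericMatrix shift_bilinear_cpp(NumericMatrix img, double drow, double dcol,
                                 double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double* p = img.begin();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = bilin(p, nr, nc, r - drow, c - dcol, fill);
  return out;
}

// Straight-ray projection of a 3D array: for each slice along dim 1, rotate the
// (dim2, dim3) plane by angle about its center and sum along dim 3. Returns an
// n1 x n2 matrix of plain voxel sums (caller scales by voxel size).
// [[Rcpp::export(name = ".project_volume_cpp")]]
NumericMatrix project_volume_cpp(NumericVector vol, double angle_deg) {
  IntegerVector d = vol.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2];
  NumericMatrix out(n1, n2);
  double a = angle_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  double c2 = (n2 - 1) / 2.0, c3 = (n3 - 1) / 2.0;
  const double* v = vol.begin();
  std::vector<double> slice(n2 * n3);
  for (int i = 0; i < n1; ++i) {
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        slice[j + n2 * k] = v[i + n1 * (j + n2 * k)];
    for (int j = 0; j < n2; ++j) {       // output detector bin (row coord)
      double acc = 0.0, dj = j - c2;
      for (int k = 0; k < n3; ++k) {     // integrate along rotated dim 3
        double dk = k - c3;
        double sr = ca * dj + sa * dk + c2;
        double sc = -sa * dj + ca * dk + c3;
        acc += bilin(slice.data(), n2, n3, sr, sc, 0.0);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

// Quality-guided flood-fill phase unwrapping. Quality = negative local variance
// of wrapped first differences; highest-quality pixels unwrapped first.
// Output is congruent to the input mod 2*pi pixelwise.
// [[Rcpp::export(name = ".unwrap_qg_cpp")]]
NumericMatrix unwrap_qg_cpp(NumericMatrix w) {
  int nr = w.nrow(), nc = w.ncol(), n = nr * nc;
  std::vector<double> qual(n, 0.0);
  // quality from variance of wrapped gradients in a 3x3 neighbourhood
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0, s2 = 0; int m = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
          if (rr + 1 < nr) {
            double g = wrap_pi(w(rr + 1, cc) - w(rr, cc));
            s += g; s2 += g * g; ++m;
          }
          if (cc + 1 < nc) {
            double g = wrap_pi(w(rr, cc + 1) - w(rr, cc));
            s += g; s2 += g * g; ++m;
          }
        }
      qual[r + nr * c] = m > 0 ? -(s2 / m - (s / m) * (s / m)) : -1e30;
    }
  NumericMatrix out(nr, nc);
  std::vector<char> solved(n, 0);
  typedef std::tuple<double, int, int> Node; // quality, idx, source idx
  std::priority_queue<Node> pq;
  int start = 0;
  for (int i = 1; i < n; ++i) if (qual[i] > qual[start]) start = i;
  out[start] = w[start];
  solved[start] = 1;
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  int sr0 = start % nr, sc0 = start / nr;
  for (int t = 0; t < 4; ++t) {
    int rr = sr0 + dr[t], cc = sc0 + dc[t];
    if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
    int idx = rr + nr * cc;
    pq.push(Node(qual[idx], idx, start));
  }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int idx = std::get<1>(nd), src = std::get<2>(nd);
    if (solved[idx]) continue;
    out[idx] = out[src] + wrap_pi(w[idx] - w[src]);
    solved[idx] = 1;
    int r = idx % nr, c = idx / nr;
    for (int t = 0; t < 4; ++t) {
      int rr = r + dr[t], cc = c + dc[t];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      int j = rr + nr * cc;
      if (!solved[j]) pq.push(Node(qual[j], j, idx));
    }
  }
  return out;
}

// 6-connected component labelling of a 3D logical array.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2], n = n1 * n2 * n3;
  IntegerVector lab(n, 0);
  lab.attr("dim") = d;
  int cur = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.push_back(i);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p % n1, rest = p / n1, y = rest % n2, z = rest / n2;
      const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int t = 0; t < 6; ++t) {
        int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= n1 || yy >= n2 || zz >= n3) continue;
        int q = xx + n1 * (yy + n2 * zz);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Fill interior cavities of a 3D mask: background voxels not 6-connected to the
// array border are set TRUE.
// [[Rcpp::export(name = ".fill_holes3d_cpp")]]
LogicalVector fill_holes3d_cpp(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2], n = n1 * n2 * n3;
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        if (x > 0 && x < n1 - 1 && y > 0 && y < n2 - 1 && z > 0 && z < n3 - 1)
          continue;
        int i = x + n1 * (y + n2 * z);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int x = p % n1, rest = p / n1, y = rest % n2, z = rest / n2;
    const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int t = 0; t < 6; ++t) {
      int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= n1 || yy >= n2 || zz >= n3) continue;
      int q = xx + n1 * (yy + n2 * zz);
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  out.attr("dim") = d;
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Separable 3D convolution with the same odd-length 1D kernel along each axis,
// reflected boundary (d c b a | a b c d | d c b a).
// [[Rcpp::export(name = ".sepconv3_cpp")]]
NumericVector sepconv3_cpp(NumericVector vol, NumericVector kern) {
  IntegerVector d = vol.attr("dim");
  int n1 = d[0], n2 = d[1], n3 = d[2], n = n1 * n2 * n3;
  int kl = kern.size(), kh = (kl - 1) / 2;
  NumericVector a = clone(vol), b(n);
  b.attr("dim") = d;
  auto reflect = [](int i, int m) {
    while (i < 0 || i >= m) { if (i < 0) i = -i - 1; if (i >= m) i = 2 * m - 1 - i; }
    return i;
  };
  // axis 1
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        double acc = 0;
        for (int t = -kh; t <= kh; ++t)
          acc += kern[t + kh] * a[reflect(x + t, n1) + n1 * (y + n2 * z)];
        b[x + n1 * (y + n2 * z)] = acc;
      }
  // axis 2
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        double acc = 0;
        for (int t = -kh; t <= kh; ++t)
          acc += kern[t + kh] * b[x + n1 * (reflect(y + t, n2) + n2 * z)];
        a[x + n1 * (y + n2 * z)] = acc;
      }
  // axis 3
  for (int z = 0; z < n3; ++z)
    for (int y = 0; y < n2; ++y)
      for (int x = 0; x < n1; ++x) {
        double acc = 0;
        for (int t = -kh; t <= kh; ++t)
          acc += kern[t + kh] * a[x + n1 * (y + n2 * reflect(z + t, n3))];
        b[x + n1 * (y + n2 * z)] = acc;
      }
  return b;
}
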