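// Low-level array kernels: separable 3D convolution (reflect boundary),
// batched symmetric 3x3 eigen-decomposition (Jacobi), and connected
// component labelling on voxel masks.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Convolve a 3D array with a 1D kernel along one axis (0,1,2), reflecting at
// the boundary. Kernel length must be odd; centre at (len-1)/2.
// [[Rcpp::export(name = ".conv3Axis")]]
NumericVector conv3_axis(NumericVector vol, IntegerVector dims, NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size(), kh = (klen - 1) / 2;
  NumericVector out(vol.size());
  const int n[3] = {nx, ny, nz};
  const int stride[3] = {1, nx, nx * ny};
  const int na = n[axis], sa = stride[axis];

  // iterate over all lines along `axis`
  int n1, n2, s1, s2;
  if (axis == 0)      { n1 = ny; s1 = stride[1]; n2 = nz; s2 = stride[2]; }
  else if (axis == 1) { n1 = nx; s1 = stride[0]; n2 = nz; s2 = stride[2]; }
  else                { n1 = nx; s1 = stride[0]; n2 = ny; s2 = stride[1]; }

  std::vector<double> line(na);
  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      const int base = i1 * s1 + i2 * s2;
      for (int a = 0; a < na; ++a) line[a] = vol[base + a * sa];
      for (int a = 0; a < na; ++a) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int idx = a + k - kh;
          // reflect (mirror without repeating the edge sample when possible)
          while (idx < 0 || idx >= na) {
            if (idx < 0) idx = -idx;
            if (idx >= na) idx = 2 * (na - 1) - idx;
            if (na == 1) { idx = 0; break; }
          }
          acc += kernel[k] * line[idx];
        }
        out[base + a * sa] = acc;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Batched symmetric 3x3 eigen-decomposition by cyclic Jacobi.
// Input: nVox x 6 matrix with columns (Jxx, Jyy, Jzz, Jxy, Jxz, Jyz).
// Output: list(values = nVox x 3 sorted descending,
//              vmin = nVox x 3 eigenvector of the smallest eigenvalue,
//              vmax = nVox x 3 eigenvector of the largest eigenvalue).
// [[Rcpp::export(name = ".eigSym3Batch")]]
List eig_sym3_batch(NumericMatrix comps) {
  const int n = comps.nrow();
  NumericMatrix values(n, 3), vmin(n, 3), vmax(n, 3);
  for (int i = 0; i < n; ++i) {
    double A[3][3] = {
      {comps(i, 0), comps(i, 3), comps(i, 4)},
      {comps(i, 3), comps(i, 1), comps(i, 5)},
      {comps(i, 4), comps(i, 5), comps(i, 2)}};
    double Q[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int sweep = 0; sweep < 30; ++sweep) {
      double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
      if (off < 1e-300) break;
      double scale = std::fabs(A[0][0]) + std::fabs(A[1][1]) + std::fabs(A[2][2]) + off;
      if (off <= 1e-15 * scale) break;
      for (int p = 0; p < 2; ++p) for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) <= 1e-300) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double qkp = Q[k][p], qkq = Q[k][q];
          Q[k][p] = c * qkp - s * qkq;
          Q[k][q] = s * qkp + c * qkq;
        }
      }
    }
    // sort eigenvalues descending
    int ord[3] = {0, 1, 2};
    double ev[3] = {A[0][0], A[1][1], A[2][2]};
    for (int a = 0; a < 2; ++a) for (int b = a + 1; b < 3; ++b)
      if (ev[ord[b]] > ev[ord[a]]) std::swap(ord[a], ord[b]);
    for (int a = 0; a < 3; ++a) values(i, a) = ev[ord[a]];
    for (int k = 0; k < 3; ++k) {
      vmax(i, k) = Q[k][ord[0]];
      vmin(i, k) = Q[k][ord[2]];
    }
  }
  return List::create(_["values"] = values, _["vmin"] = vmin, _["vmax"] = vmax);
}

// Connected-component labelling of a logical mask (stored as int 0/1).
// connectivity: 6 or 26. Returns integer array, 0 = background, components
// numbered from 1 in discovery order.
// [[Rcpp::export(name = ".ccLabel3")]]
IntegerVector cc_label3(IntegerVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
      if (connectivity == 6 && manh != 1) continue;
      offs.push_back({dx, dy, dz});
    }
  int comp = 0;
  std::queue<int> q;
  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++comp;
    lab[start] = comp;
    q.push((int)start);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / (nx * ny);
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int nb = xx + nx * (yy + ny * zz);
        if (mask[nb] && !lab[nb]) { lab[nb] = comp; q.push(nb); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
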