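#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Unfold a (nx, ny, nz, c) array into the column matrix of a valid 3D
// convolution with cubic kernel k. Row r = output voxel (column-major, x
// fastest); column j = ch * k^3 + dx + k*(dy + k*dz). The weight matrix of a
// convolution layer uses the same row ordering, so the convolution is a
// single GEMM on the result.
// [[Rcpp::export(rng = false)]]
NumericMatrix im2col3d(NumericVector x, IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], c = dims[3];
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("input grid smaller than kernel");
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  const int k3 = k * k * k;
  NumericMatrix out(nout, (R_xlen_t)k3 * c);
  const double* px = REAL(x);
  double* po = REAL(out);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t oxy = (R_xlen_t)ox * oy;
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t chbase = (R_xlen_t)ch * nxy * nz;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const R_xlen_t col = (R_xlen_t)ch * k3 + dx + k * (dy + k * dz);
          double* pcol = po + col * nout;
          for (int z = 0; z < oz; ++z)
            for (int y = 0; y < oy; ++y) {
              const double* src = px + chbase + (z + dz) * nxy + (R_xlen_t)(y + dy) * nx + dx;
              std::memcpy(pcol + (R_xlen_t)z * oxy + (R_xlen_t)y * ox, src,
                          (size_t)ox * sizeof(double));
            }
        }
  }
  return out;
}

// Adjoint of im2col3d: scatter-add a column matrix back onto the input grid.
// Used for the data gradient of a valid convolution.
// [[Rcpp::export(rng = false)]]
NumericVector col2im3d(NumericMatrix cols, IntegerVector dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], c = dims[3];
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("input grid smaller than kernel");
  const R_xlen_t nout = (R_xlen_t)ox * oy * oz;
  const int k3 = k * k * k;
  if (cols.nrow() != nout || cols.ncol() != (R_xlen_t)k3 * c)
    stop("column matrix does not match grid dimensions");
  NumericVector x((R_xlen_t)nx * ny * nz * c);
  double* px = REAL(x);
  const double* po = REAL(cols);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t oxy = (R_xlen_t)ox * oy;
  for (int ch = 0; ch < c; ++ch) {
    const R_xlen_t chbase = (R_xlen_t)ch * nxy * nz;
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const R_xlen_t col = (R_xlen_t)ch * k3 + dx + k * (dy + k * dz);
          const double* pcol = po + col * nout;
          for (int z = 0; z < oz; ++z)
            for (int y = 0; y < oy; ++y) {
              double* dst = px + chbase + (z + dz) * nxy + (R_xlen_t)(y + dy) * nx + dx;
              const double* src = pcol + (R_xlen_t)z * oxy + (R_xlen_t)y * ox;
              for (int i = 0; i < ox; ++i) dst[i] += src[i];
            }
        }
  }
  x.attr("dim") = dims;
  return x;
}

// Label connected components of the non-zero voxels of a 3D integer grid
// under 6/18/26-connectivity. Returns an integer grid: 0 background,
// 1..n component ids (breadth-first order).
// [[Rcpp::export(rng = false)]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> off_x, off_y, off_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        if ((connectivity == 6 && d > 1) || (connectivity == 18 && d > 2)) continue;
        off_x.push_back(dx); off_y.push_back(dy); off_z.push_back(dz);
      }
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int* pm = INTEGER(mask);
  int* pl = INTEGER(lab);
  std::vector<R_xlen_t> queue;
  int next = 0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++next;
    pl[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      const R_xlen_t v = queue[head++];
      const int z = (int)(v / nxy);
      const int y = (int)((v - (R_xlen_t)z * nxy) / nx);
      const int x = (int)(v - (R_xlen_t)z * nxy - (R_xlen_t)y * nx);
      for (size_t o = 0; o < off_x.size(); ++o) {
        const int xx = x + off_x[o], yy = y + off_y[o], zz = z + off_z[o];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        const R_xlen_t w = xx + (R_xlen_t)yy * nx + (R_xlen_t)zz * nxy;
        if (pm[w] != 0 && pl[w] == 0) { pl[w] = next; queue.push_back(w); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Direct valid 3D convolution: y = conv(x, W) + b, W as (k^3 * c_in, c_out)
// with row index ci * k^3 + dx + k*(dy + k*dz). Buffer-free; inner loops run
// along the contiguous x axis.
// [[Rcpp::export(rng = false)]]
NumericVector conv3d_direct(NumericVector x, IntegerVector dims,
                            NumericMatrix W, NumericVector b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("input grid smaller than kernel");
  const int k3 = k * k * k;
  const int cout = W.ncol();
  if (W.nrow() != k3 * cin) stop("weight/input channel mismatch");
  NumericVector y((R_xlen_t)ox * oy * oz * cout);
  const double* px = REAL(x);
  const double* pw = REAL(W);
  const double* pb = REAL(b);
  double* py = REAL(y);
  const R_xlen_t nxy = (R_xlen_t)nx * ny, oxy = (R_xlen_t)ox * oy;
  for (int co = 0; co < cout; ++co) {
    const double* wc = pw + (R_xlen_t)co * k3 * cin;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy) {
        double* orow = py + (R_xlen_t)co * oz * oxy + z * oxy + (R_xlen_t)yy * ox;
        const double bco = pb[co];
        for (int i = 0; i < ox; ++i) orow[i] = bco;
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = px + (R_xlen_t)ci * nxy * nz;
          for (int dz = 0; dz < k; ++dz)
            for (int dy = 0; dy < k; ++dy) {
              const double* xrow = xc + (z + dz) * nxy + (R_xlen_t)(yy + dy) * nx;
              const double* wrow = wc + ci * k3 + k * (dy + k * dz);
              for (int dx = 0; dx < k; ++dx) {
                const double w = wrow[dx];
                const double* xr = xrow + dx;
                for (int i = 0; i < ox; ++i) orow[i] += w * xr[i];
              }
            }
        }
      }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return y;
}

// Fused backward of the direct convolution: given x and dL/dy, produce
// dL/dx, dL/dW and dL/db in one pass.
// [[Rcpp::export(rng = false)]]
List conv3d_direct_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                       NumericVector dy, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  const int k3 = k * k * k;
  const int cout = W.ncol();
  if (W.nrow() != k3 * cin) stop("weight/input channel mismatch");
  NumericVector dx((R_xlen_t)nx * ny * nz * cin);
  NumericMatrix dW(k3 * cin, cout);
  NumericVector db(cout);
  const double* px = REAL(x);
  const double* pw = REAL(W);
  const double* pdy = REAL(dy);
  double* pdx = REAL(dx);
  double* pdW = REAL(dW);
  double* pdb = REAL(db);
  const R_xlen_t nxy = (R_xlen_t)nx * ny, oxy = (R_xlen_t)ox * oy;
  for (int co = 0; co < cout; ++co) {
    const double* wc = pw + (R_xlen_t)co * k3 * cin;
    double* dwc = pdW + (R_xlen_t)co * k3 * cin;
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy) {
        const double* gr = pdy + (R_xlen_t)co * oz * oxy + z * oxy +
          (R_xlen_t)yy * ox;
        double s = 0.0;
        for (int i = 0; i < ox; ++i) s += gr[i];
        pdb[co] += s;
        for (int ci = 0; ci < cin; ++ci) {
          const double* xc = px + (R_xlen_t)ci * nxy * nz;
          double* dxc = pdx + (R_xlen_t)ci * nxy * nz;
          for (int dz = 0; dz < k; ++dz)
            for (int dy_ = 0; dy_ < k; ++dy_) {
              const R_xlen_t roff = (z + dz) * nxy + (R_xlen_t)(yy + dy_) * nx;
              const double* xrow = xc + roff;
              double* dxrow = dxc + roff;
              const double* wrow = wc + ci * k3 + k * (dy_ + k * dz);
              double* dwrow = dwc + ci * k3 + k * (dy_ + k * dz);
              for (int dx_ = 0; dx_ < k; ++dx_) {
                const double w = wrow[dx_];
                double acc = 0.0;
                double* dxr = dxrow + dx_;
                const double* xr = xrow + dx_;
                for (int i = 0; i < ox; ++i) {
                  dxr[i] += w * gr[i];
                  acc += xr[i] * gr[i];
                }
                dwrow[dx_] += acc;
              }
            }
        }
      }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
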