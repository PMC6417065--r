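#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Quantized ROIs are passed as integer arrays in (z, y, x) order
// (column-major, z fastest), with 0 marking out-of-mask voxels and
// levels 1..L inside the mask.  Direction matrices have one row per
// offset, columns (dz, dy, dx).

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector arr, IntegerVector dim,
                              IntegerMatrix dirs, int L) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int nd = dirs.nrow();
  NumericVector out(L * L * nd);
  for (int d = 0; d < nd; ++d) {
    int dz = dirs(d, 0), dy = dirs(d, 1), dx = dirs(d, 2);
    double *slab = &out[0] + (R_xlen_t)d * L * L;
    for (int x = 0; x < nx; ++x) {
      int x2 = x + dx;
      if (x2 < 0 || x2 >= nx) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int z = 0; z < nz; ++z) {
          int z2 = z + dz;
          if (z2 < 0 || z2 >= nz) continue;
          int a = arr[idx3(z, y, x, nz, ny)];
          if (a == 0) continue;
          int b = arr[idx3(z2, y2, x2, nz, ny)];
          if (b == 0) continue;
          // symmetric: record both orderings
          slab[(a - 1) + L * (b - 1)] += 1.0;
          slab[(b - 1) + L * (a - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(L, L, nd);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector arr, IntegerVector dim,
                               IntegerMatrix dirs, int L) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int nd = dirs.nrow();
  int maxlen = nz + ny + nx;  // safe bound on any straight run
  NumericVector out((R_xlen_t)L * maxlen * nd);
  for (int d = 0; d < nd; ++d) {
    int dz = dirs(d, 0), dy = dirs(d, 1), dx = dirs(d, 2);
    double *slab = &out[0] + (R_xlen_t)d * L * maxlen;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int a = arr[idx3(z, y, x, nz, ny)];
          if (a == 0) continue;
          // run start: predecessor along -d is outside grid/mask or differs
          int zp = z - dz, yp = y - dy, xp = x - dx;
          if (zp >= 0 && zp < nz && yp >= 0 && yp < ny && xp >= 0 && xp < nx &&
              arr[idx3(zp, yp, xp, nz, ny)] == a)
            continue;
          int len = 1;
          int zc = z + dz, yc = y + dy, xc = x + dx;
          while (zc >= 0 && zc < nz && yc >= 0 && yc < ny && xc >= 0 &&
                 xc < nx && arr[idx3(zc, yc, xc, nz, ny)] == a) {
            ++len;
            zc += dz; yc += dy; xc += dx;
          }
          slab[(a - 1) + L * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(L, maxlen, nd);
  return out;
}

// Connected zones of equal level; connectivity given by the half
// neighborhood in `dirs` (both signs are explored).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector arr, IntegerVector dim,
                              IntegerMatrix dirs) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int nd = dirs.nrow();
  R_xlen_t n = arr.size();
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (seen[start] || arr[start] == 0) continue;
    int lev = arr[start];
    int size = 0;
    stack.clear();
    stack.push_back((int)start);
    seen[start] = 1;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      ++size;
      int x = v / (nz * ny), rem = v % (nz * ny);
      int y = rem / nz, z = rem % nz;
      for (int d = 0; d < nd; ++d)
        for (int s = -1; s <= 1; s += 2) {
          int z2 = z + s * dirs(d, 0), y2 = y + s * dirs(d, 1),
              x2 = x + s * dirs(d, 2);
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          int w = idx3(z2, y2, x2, nz, ny);
          if (!seen[w] && arr[w] == lev) {
            seen[w] = 1;
            stack.push_back(w);
          }
        }
    }
    zl.push_back(lev);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}

// Per-level neighbourhood statistics: n_i voxels of level i that have at
// least one in-mask neighbour, and s_i = sum |i - mean(in-mask neighbours)|.
// `dirs` is the full neighbourhood (26 offsets in 3D, 8 in 2D).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector arr, IntegerVector dim,
                        IntegerMatrix dirs, int L) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int nd = dirs.nrow();
  NumericMatrix out(L, 2);  // columns: n_i, s_i
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int a = arr[idx3(z, y, x, nz, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int d = 0; d < nd; ++d) {
          int z2 = z + dirs(d, 0), y2 = y + dirs(d, 1), x2 = x + dirs(d, 2);
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          int b = arr[idx3(z2, y2, x2, nz, ny)];
          if (b > 0) {
            sum += b;
            ++cnt;
          }
        }
        if (cnt > 0) {
          out(a - 1, 0) += 1.0;
          out(a - 1, 1) += std::abs((double)a - sum / cnt);
        }
      }
  return out;
}
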