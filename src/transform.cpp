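#include <Rcpp.h>
using namespace Rcpp;

// Trilinear resampling of a 3D array under an affine map.
// out(x) = in(A %*% (x - c_out) + c_in + t), 0-based voxel coordinates.
// Out-of-domain samples take `fill`.  A is row-major 3x3 passed as 9 doubles.
// [[Rcpp::export(name = ".affine_resample_cpp")]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector A, NumericVector t,
                                  NumericVector c_out, NumericVector c_in,
                                  double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  const double a00 = A[0], a01 = A[1], a02 = A[2];
  const double a10 = A[3], a11 = A[4], a12 = A[5];
  const double a20 = A[6], a21 = A[7], a22 = A[8];
  const double *v = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    const double dz = z - c_out[2];
    for (int y = 0; y < ny; ++y) {
      const double dy = y - c_out[1];
      for (int x = 0; x < nx; ++x) {
        const double dx = x - c_out[0];
        const double sx = a00 * dx + a01 * dy + a02 * dz + c_in[0] + t[0];
        const double sy = a10 * dx + a11 * dy + a12 * dz + c_in[1] + t[1];
        const double sz = a20 * dx + a21 * dy + a22 * dz + c_in[2] + t[2];
        double val;
        if (sx < 0 || sy < 0 || sz < 0 ||
            sx > nx - 1 || sy > ny - 1 || sz > nz - 1) {
          val = fill;
        } else {
          // clamp so samples landing exactly on the last plane stay in-domain
          const int ix = std::min((int)std::floor(sx), nx - 2);
          const int iy = std::min((int)std::floor(sy), ny - 2);
          const int iz = std::min((int)std::floor(sz), nz - 2);
          const double fx = sx - ix, fy = sy - iy, fz = sz - iz;
          const std::size_t b = (std::size_t)ix +
            (std::size_t)nx * ((std::size_t)iy + (std::size_t)ny * (std::size_t)iz);
          const std::size_t sxy = (std::size_t)nx * (std::size_t)ny;
          const double c000 = v[b],            c100 = v[b + 1];
          const double c010 = v[b + nx],       c110 = v[b + nx + 1];
          const double c001 = v[b + sxy],      c101 = v[b + sxy + 1];
          const double c011 = v[b + sxy + nx], c111 = v[b + sxy + nx + 1];
          const double c00 = c000 * (1 - fx) + c100 * fx;
          const double c10 = c010 * (1 - fx) + c110 * fx;
          const double c01 = c001 * (1 - fx) + c101 * fx;
          const double c11 = c011 * (1 - fx) + c111 * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        o[(std::size_t)x + (std::size_t)nx * ((std::size_t)y + (std::size_t)ny * (std::size_t)z)] = val;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Accumulate a small box into a large volume at integer offset (0-based),
// clipping at the borders.  Used by the tomogram rasterizer.
// [[Rcpp::export(name = ".accumulate_box_cpp")]]
void accumulate_box_cpp(NumericVector tomo, IntegerVector tdims,
                        NumericVector box, IntegerVector bdims,
                        IntegerVector offset) {
  const int tx = tdims[0], ty = tdims[1], tz = tdims[2];
  const int bx = bdims[0], by = bdims[1], bz = bdims[2];
  double *tp = tomo.begin();
  const double *bp = box.begin();
  for (int z = 0; z < bz; ++z) {
    const int zz = z + offset[2];
    if (zz < 0 || zz >= tz) continue;
    for (int y = 0; y < by; ++y) {
      const int yy = y + offset[1];
      if (yy < 0 || yy >= ty) continue;
      for (int x = 0; x < bx; ++x) {
        const int xx = x + offset[0];
        if (xx < 0 || xx >= tx) continue;
        tp[(std::size_t)xx + (std::size_t)tx * ((std::size_t)yy + (std::size_t)ty * (std::size_t)zz)] +=
          bp[(std::size_t)x + (std::size_t)bx * ((std::size_t)y + (std::size_t)by * (std::size_t)z)];
      }
    }
  }
}
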