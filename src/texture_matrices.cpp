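// Gray-level matrix construction for 3D texture features and mesh geometry
// for shape features. The lattice is an integer array with in-mask voxels
// carrying gray levels 1..nbins and out-of-mask voxels 0.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
using namespace Rcpp;

// 13 unique direction offsets covering the 26-neighborhood up to sign.
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

static inline int at(const IntegerVector& lat, int nx, int ny, int nz,
                     int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return lat[x + nx * (y + ny * z)];
}

// Symmetric co-occurrence matrices at distance 1, one per direction:
// returns nbins x nbins x 13 counts.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lat, IntegerVector dims, int nbins) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nbins * nbins * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* M = &out[d * nbins * nbins];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(lat, nx, ny, nz, x, y, z);
          if (!a) continue;
          int b = at(lat, nx, ny, nz, x + dx, y + dy, z + dz);
          if (!b) continue;
          M[(a - 1) + nbins * (b - 1)] += 1.0;
          M[(b - 1) + nbins * (a - 1)] += 1.0;  // symmetric
        }
  }
  out.attr("dim") = IntegerVector::create(nbins, nbins, 13);
  return out;
}

// Run-length matrices, one per direction: nbins x maxrun x 13 counts.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lat, IntegerVector dims, int nbins) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nmax = std::max(nx, std::max(ny, nz));
  NumericVector out(nbins * nmax * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double* M = &out[d * nbins * nmax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = at(lat, nx, ny, nz, x, y, z);
          if (!a) continue;
          // run start: predecessor along the direction differs
          if (at(lat, nx, ny, nz, x - dx, y - dy, z - dz) == a) continue;
          int len = 1, cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(lat, nx, ny, nz, cx, cy, cz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          M[(a - 1) + nbins * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nbins, nmax, 13);
  return out;
}

// Size-zone matrix: 26-connected equal-level zones; nbins x maxzonesize.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector lat, IntegerVector dims, int nbins) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::map<std::pair<int,int>, double> zones;
  int maxsize = 1;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (seen[i] || lat[i] == 0) continue;
    int lev = lat[i];
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      ++size;
      int x = j % nx, y = (j / nx) % ny, z = j / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            int k = X + nx * (Y + ny * Z);
            if (!seen[k] && lat[k] == lev) { seen[k] = 1; stack.push_back(k); }
          }
    }
    zones[std::make_pair(lev, size)] += 1.0;
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix M(nbins, maxsize);
  for (std::map<std::pair<int,int>, double>::iterator it = zones.begin();
       it != zones.end(); ++it)
    M(it->first.first - 1, it->first.second - 1) = it->second;
  return M;
}

// Dependence matrix: for each in-mask voxel, the number of 26-neighbors
// (in-mask) with identical gray level (alpha = 0); nbins x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lat, IntegerVector dims, int nbins) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nbins, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(lat, nx, ny, nz, x, y, z);
        if (!a) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              if (at(lat, nx, ny, nz, x + dx, y + dy, z + dz) == a) ++dep;
            }
        M(a - 1, dep) += 1.0;
      }
  return M;
}

// Neighborhood gray-tone difference: per level i, n_i (voxel count) and
// s_i = sum over those voxels of |level - mean of in-mask 26-neighbors|.
// Voxels with no in-mask neighbor contribute to neither.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lat, IntegerVector dims, int nbins) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(nbins, 2);  // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = at(lat, nx, ny, nz, x, y, z);
        if (!a) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int b = at(lat, nx, ny, nz, x + dx, y + dy, z + dz);
              if (b) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        M(a - 1, 0) += 1.0;
        M(a - 1, 1) += std::fabs(a - sum / cnt);
      }
  return M;
}

// ---------------------------------------------------------------------------
// Mesh geometry: marching tetrahedra over the binary mask (iso-level 0.5,
// vertices at cell-edge midpoints). Returns total triangle area and the
// enclosed volume (triangles oriented outward numerically). The mask must be
// zero-padded by the caller so the surface closes.
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(IntegerVector mask, IntegerVector dims,
                                   NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner index offsets
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tetrahedra decomposition of the cube (consistent across cells)
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  double area = 0.0, vol6 = 0.0;
  std::vector<double> px(8), py(8), pz(8);
  std::vector<int> inside(8);
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int X = x + corner[c][0], Y = y + corner[c][1], Z = z + corner[c][2];
          inside[c] = mask[X + nx * (Y + ny * Z)] != 0;
          nin += inside[c];
          px[c] = X * sx; py[c] = Y * sy; pz[c] = Z * sz;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4]; int cnt = 0;
          for (int k = 0; k < 4; ++k) if (inside[tets[t][k]]) vi[cnt++] = k;
          if (cnt == 0 || cnt == 4) continue;
          // centroid of inside vertices (for outward orientation)
          double cx = 0, cy = 0, cz = 0;
          for (int k = 0; k < cnt; ++k) {
            int c = tets[t][vi[k]];
            cx += px[c]; cy += py[c]; cz += pz[c];
          }
          cx /= cnt; cy /= cnt; cz /= cnt;
          // edge midpoints between inside/outside vertex pairs
          double mx[4], my[4], mz[4]; int nm = 0;
          for (int a2 = 0; a2 < 4; ++a2)
            for (int b2 = 0; b2 < 4; ++b2) {
              if (!inside[tets[t][a2]] || inside[tets[t][b2]]) continue;
              int ca = tets[t][a2], cb = tets[t][b2];
              mx[nm] = 0.5 * (px[ca] + px[cb]);
              my[nm] = 0.5 * (py[ca] + py[cb]);
              mz[nm] = 0.5 * (pz[ca] + pz[cb]);
              ++nm;
            }
          // nm is 3 (single triangle) or 4 (quad -> 2 triangles).
          // For nm == 4 order the quad so consecutive points share a tet edge:
          // crossing pairs are (i0,o0),(i0,o1),(i1,o1),(i1,o0) given the loop
          // order above is (i0o0,i0o1,i1o0,i1o1) for cnt==2 -> swap last two.
          if (nm == 4) { std::swap(mx[2], mx[3]); std::swap(my[2], my[3]); std::swap(mz[2], mz[3]); }
          int ntri = (nm == 3) ? 1 : 2;
          for (int q = 0; q < ntri; ++q) {
            int i0 = 0, i1 = q + 1, i2 = q + 2;
            double ux = mx[i1] - mx[i0], uy = my[i1] - my[i0], uz = mz[i1] - mz[i0];
            double vx2 = mx[i2] - mx[i0], vy2 = my[i2] - my[i0], vz2 = mz[i2] - mz[i0];
            double nxv = uy * vz2 - uz * vy2;
            double nyv = uz * vx2 - ux * vz2;
            double nzv = ux * vy2 - uy * vx2;
            double a2n = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
            // flip so the normal points away from the inside centroid
            double wx = mx[i0] - cx, wy = my[i0] - cy, wz = mz[i0] - cz;
            double sgn = (nxv * wx + nyv * wy + nzv * wz) >= 0 ? 1.0 : -1.0;
            area += 0.5 * a2n;
            // signed volume contribution of oriented triangle (origin-based)
            double det = mx[i0] * (my[i1] * mz[i2] - mz[i1] * my[i2])
                       - my[i0] * (mx[i1] * mz[i2] - mz[i1] * mx[i2])
                       + mz[i0] * (mx[i1] * my[i2] - my[i1] * mx[i2]);
            if (sgn < 0) {
              // swapping two vertices flips the determinant sign
              det = -det;
            }
            vol6 += det;
          }
        }
      }
  return NumericVector::create(area, std::fabs(vol6) / 6.0);
}

// Largest pairwise distances between boundary voxel centers: overall 3D and
// within each axis-orthogonal plane family (matching the usual slice /
// column / row 2D diameters). Returns (d3d, d2d_z, d2d_y, d2d_x) where
// d2d_z is the max within constant-z slices, etc.
// [[Rcpp::export]]
NumericVector cpp_max_diameters(IntegerVector mask, IntegerVector dims,
                                NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> bx, by, bz;
  std::vector<int> ix, iy, iz;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!at(mask, nx, ny, nz, x, y, z)) continue;
        bool bnd = !at(mask, nx, ny, nz, x - 1, y, z) || !at(mask, nx, ny, nz, x + 1, y, z) ||
                   !at(mask, nx, ny, nz, x, y - 1, z) || !at(mask, nx, ny, nz, x, y + 1, z) ||
                   !at(mask, nx, ny, nz, x, y, z - 1) || !at(mask, nx, ny, nz, x, y, z + 1);
        if (!bnd) continue;
        bx.push_back(x * spacing[0]); by.push_back(y * spacing[1]); bz.push_back(z * spacing[2]);
        ix.push_back(x); iy.push_back(y); iz.push_back(z);
      }
  int n = bx.size();
  double d3 = 0, dz = 0, dy = 0, dx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ddx = bx[i] - bx[j], ddy = by[i] - by[j], ddz = bz[i] - bz[j];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > d3) d3 = d2;
      if (iz[i] == iz[j] && ddx * ddx + ddy * ddy > dz) dz = ddx * ddx + ddy * ddy;
      if (iy[i] == iy[j] && ddx * ddx + ddz * ddz > dy) dy = ddx * ddx + ddz * ddz;
      if (ix[i] == ix[j] && ddy * ddy + ddz * ddz > dx) dx = ddy * ddy + ddz * ddz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dz), std::sqrt(dy), std::sqrt(dx));
}
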