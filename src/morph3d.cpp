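// 3D kernels for binary-mask morphometry: exact Euclidean distance
// transform, maximal-inscribed-sphere local thickness, marching-tetrahedra
// isosurface extraction, trilinear/nearest grid resampling, separable
// 1D convolution with mirror padding, and 26-connected components.
//
// All arrays are column-major [x, y, z] (R layout); physical positions of
// voxel centers are index * spacing along each axis.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double DT_INF = 1e30;

// ---------------------------------------------------------------------------
// 1D squared distance transform along a line of parabolas
// (Felzenszwalb & Huttenlocher 2012), sample positions i * step.
// f: input squared distances, overwritten with the transform.
static void dt1d(std::vector<double>& f, int n, double step,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& out) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    double s = 0.0;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) k--; else break;
    }
    if (s <= z[k] && k == 0) {
      // q's parabola dominates everywhere so far
      v[0] = q;
      z[0] = -DT_INF;
      z[1] = DT_INF;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
      z[k + 1] = DT_INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * step;
    out[q] = dx * dx + f[v[k]];
  }
  std::copy(out.begin(), out.begin() + n, f.begin());
}

// Squared EDT of a site indicator: for every voxel, squared distance (mm^2)
// to the nearest TRUE voxel center. Returns DT_INF-sized values if no site.
static std::vector<double> edt_sq(const int* site, int nx, int ny, int nz,
                                  double sx, double sy, double sz) {
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; i++) d[i] = site[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      size_t base = (size_t)zz * nx * ny + (size_t)yy * nx;
      for (int xx = 0; xx < nx; xx++) f[xx] = d[base + xx];
      dt1d(f, nx, sx, v, z, out);
      for (int xx = 0; xx < nx; xx++) d[base + xx] = f[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = (size_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; yy++) f[yy] = d[base + (size_t)yy * nx];
      dt1d(f, ny, sy, v, z, out);
      for (int yy = 0; yy < ny; yy++) d[base + (size_t)yy * nx] = f[yy];
    }
  // pass along z
  size_t nxy = (size_t)nx * ny;
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      size_t base = (size_t)yy * nx + xx;
      for (int zz = 0; zz < nz; zz++) f[zz] = d[base + (size_t)zz * nxy];
      dt1d(f, nz, sz, v, z, out);
      for (int zz = 0; zz < nz; zz++) d[base + (size_t)zz * nxy] = f[zz];
    }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector sites, IntegerVector dim,
                      NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> d = edt_sq(LOGICAL(sites), nx, ny, nz,
                                 spacing[0], spacing[1], spacing[2]);
  size_t n = d.size();
  NumericVector res(n);
  for (size_t i = 0; i < n; i++)
    res[i] = (d[i] >= DT_INF) ? R_PosInf : std::sqrt(d[i]);
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Local thickness (maximal inscribed spheres) on an isotropic grid.
//
// mask: foreground indicator; h: isotropic spacing (mm).
// For every foreground voxel, thickness = diameter of the largest sphere
// that contains the voxel center and fits inside the foreground solid
// (union of voxel cubes). Sphere radii derive from the EDT to background
// voxel centers (r_surf = d - h/2); candidate sphere centers are
// distance-ridge voxels plus axis midpoints between adjacent ridge voxels,
// which recovers the half-voxel medial-axis quantization (peak of the
// 1-Lipschitz distance profile between two samples is (d1 + d2 + h) / 2).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  double h) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);

  // EDT to background voxel centers; treat the outside of the array as
  // background by handling borders in the ridge/painting logic: a mask
  // touching the border would otherwise have unbounded distance, so the
  // caller pads. Here: sites = background voxels.
  std::vector<int> bg(n);
  bool any_bg = false;
  for (size_t i = 0; i < n; i++) { bg[i] = !m[i]; if (bg[i]) any_bg = true; }
  if (!any_bg) stop("mask has no background; pad the volume");
  std::vector<double> dsq = edt_sq(bg.data(), nx, ny, nz, h, h, h);
  std::vector<float> d(n);
  for (size_t i = 0; i < n; i++) d[i] = (float)std::sqrt(dsq[i]);
  std::vector<double>().swap(dsq);

  size_t nxy = (size_t)nx * ny;
  // 26-neighborhood offsets and their physical lengths
  int noff[26][3]; double nlen[26]; int nc = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        noff[nc][0] = dx; noff[nc][1] = dy; noff[nc][2] = dz;
        nlen[nc] = h * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        nc++;
      }

  // ridge: fg voxel whose sphere is not contained in a neighbor's sphere
  std::vector<uint8_t> ridge(n, 0);
  const double eps = 1e-9;
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        size_t i = (size_t)zz * nxy + (size_t)yy * nx + xx;
        if (!m[i]) continue;
        bool isridge = true;
        for (int k = 0; k < 26; k++) {
          int qx = xx + noff[k][0], qy = yy + noff[k][1], qz = zz + noff[k][2];
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          size_t q = (size_t)qz * nxy + (size_t)qy * nx + qx;
          if (d[q] >= d[i] + nlen[k] - eps) { isridge = false; break; }
        }
        if (isridge) ridge[i] = 1;
      }

  // candidates: (cx, cy, cz) in mm, surface radius r in mm
  struct Cand { float x, y, z, r; };
  std::vector<Cand> cand;
  cand.reserve(1024);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++) {
        size_t i = (size_t)zz * nxy + (size_t)yy * nx + xx;
        if (!ridge[i]) continue;
        double r = d[i] - 0.5 * h;
        if (r <= 0) continue;
        Cand c; c.x = xx * h; c.y = yy * h; c.z = zz * h; c.r = (float)r;
        cand.push_back(c);
        // axis midpoints with the next ridge voxel along +x/+y/+z
        const int ax[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
        for (int a = 0; a < 3; a++) {
          int qx = xx + ax[a][0], qy = yy + ax[a][1], qz = zz + ax[a][2];
          if (qx >= nx || qy >= ny || qz >= nz) continue;
          size_t q = (size_t)qz * nxy + (size_t)qy * nx + qx;
          if (!ridge[q]) continue;
          if (std::fabs((double)d[i] - (double)d[q]) < h * 0.999) {
            Cand cm;
            cm.x = (float)((xx + 0.5 * ax[a][0]) * h);
            cm.y = (float)((yy + 0.5 * ax[a][1]) * h);
            cm.z = (float)((zz + 0.5 * ax[a][2]) * h);
            cm.r = (float)(0.5 * ((double)d[i] + (double)d[q]));
            if (cm.r > c.r) cand.push_back(cm);
          }
        }
      }

  std::sort(cand.begin(), cand.end(),
            [](const Cand& a, const Cand& b) { return a.r > b.r; });

  // initialize with each voxel's own inscribed sphere, then paint
  NumericVector th(n);
  double* t = REAL(th);
  for (size_t i = 0; i < n; i++)
    t[i] = m[i] ? std::max(0.0, 2.0 * ((double)d[i] - 0.5 * h)) : 0.0;

  for (const Cand& c : cand) {
    double r = c.r, diam = 2.0 * r, r2 = r * r + 1e-9;
    int x0 = std::max(0, (int)std::ceil((c.x - r) / h - 1e-9));
    int x1 = std::min(nx - 1, (int)std::floor((c.x + r) / h + 1e-9));
    int y0 = std::max(0, (int)std::ceil((c.y - r) / h - 1e-9));
    int y1 = std::min(ny - 1, (int)std::floor((c.y + r) / h + 1e-9));
    int z0 = std::max(0, (int)std::ceil((c.z - r) / h - 1e-9));
    int z1 = std::min(nz - 1, (int)std::floor((c.z + r) / h + 1e-9));
    for (int zz = z0; zz <= z1; zz++) {
      double dz = zz * h - c.z;
      for (int yy = y0; yy <= y1; yy++) {
        double dy = yy * h - c.y;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        size_t base = (size_t)zz * nxy + (size_t)yy * nx;
        for (int xx = x0; xx <= x1; xx++) {
          double dx = xx * h - c.x;
          if (dx * dx + dyz > r2) continue;
          size_t i = base + xx;
          if (m[i] && t[i] < diam) t[i] = diam;
        }
      }
    }
  }
  th.attr("dim") = dim;
  return th;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a scalar field: triangulated isosurface at `level`
// with linear interpolation along tetrahedron edges. Inside = value > level.
// Returns total area (mm^2) and optionally the triangle soup.

struct P3 { double x, y, z; };

static inline P3 interp_edge(const P3& a, const P3& b, double fa, double fb,
                             double level) {
  double t = (level - fa) / (fb - fa);
  P3 p;
  p.x = a.x + t * (b.x - a.x);
  p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z);
  return p;
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, IntegerVector dim,
                    NumericVector spacing, double level, bool want_mesh) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double* f = REAL(field);
  size_t nxy = (size_t)nx * ny;

  // cube corner offsets, bit order (x, y, z)
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra around the 0-6 diagonal
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

  double area = 0.0;
  std::vector<double> verts;  // triangle soup, 9 doubles per triangle

  P3 cp[8]; double cf[8];
  for (int zz = 0; zz < nz - 1; zz++)
    for (int yy = 0; yy < ny - 1; yy++)
      for (int xx = 0; xx < nx - 1; xx++) {
        // quick reject on uniform cubes
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; c++) {
          size_t i = (size_t)(zz + corner[c][2]) * nxy +
                     (size_t)(yy + corner[c][1]) * nx + (xx + corner[c][0]);
          cf[c] = f[i];
          if (cf[c] > level) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int c = 0; c < 8; c++) {
          cp[c].x = (xx + corner[c][0]) * sx;
          cp[c].y = (yy + corner[c][1]) * sy;
          cp[c].z = (zz + corner[c][2]) * sz;
        }
        for (int tt = 0; tt < 6; tt++) {
          const int* tv = tets[tt];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; k++) {
            if (cf[tv[k]] > level) in[nin++] = tv[k];
            else out[nout++] = tv[k];
          }
          if (nin == 0 || nin == 4) continue;
          P3 tri[4]; int ntri = 0; // up to 2 triangles (4 poly points)
          if (nin == 1) {
            for (int k = 0; k < 3; k++)
              tri[k] = interp_edge(cp[in[0]], cp[out[k]],
                                   cf[in[0]], cf[out[k]], level);
            ntri = 3;
          } else if (nin == 3) {
            for (int k = 0; k < 3; k++)
              tri[k] = interp_edge(cp[out[0]], cp[in[k]],
                                   cf[out[0]], cf[in[k]], level);
            ntri = 3;
          } else { // nin == 2: quad
            tri[0] = interp_edge(cp[in[0]], cp[out[0]], cf[in[0]], cf[out[0]], level);
            tri[1] = interp_edge(cp[in[0]], cp[out[1]], cf[in[0]], cf[out[1]], level);
            tri[2] = interp_edge(cp[in[1]], cp[out[1]], cf[in[1]], cf[out[1]], level);
            tri[3] = interp_edge(cp[in[1]], cp[out[0]], cf[in[1]], cf[out[0]], level);
            ntri = 4;
          }
          if (ntri == 3) {
            area += tri_area(tri[0], tri[1], tri[2]);
            if (want_mesh)
              for (int k = 0; k < 3; k++) {
                verts.push_back(tri[k].x); verts.push_back(tri[k].y);
                verts.push_back(tri[k].z);
              }
          } else {
            area += tri_area(tri[0], tri[1], tri[2]);
            area += tri_area(tri[0], tri[2], tri[3]);
            if (want_mesh) {
              const int idx[6] = {0, 1, 2, 0, 2, 3};
              for (int k = 0; k < 6; k++) {
                verts.push_back(tri[idx[k]].x); verts.push_back(tri[idx[k]].y);
                verts.push_back(tri[idx[k]].z);
              }
            }
          }
        }
      }

  if (!want_mesh) return List::create(Named("area") = area);
  size_t ntri = verts.size() / 9;
  NumericMatrix vm(3, 3 * ntri);
  std::copy(verts.begin(), verts.end(), vm.begin());
  return List::create(Named("area") = area, Named("vertices") = vm);
}

// ---------------------------------------------------------------------------
// Grid-to-grid resampling, cell-centre aligned: output voxel i sits at
// physical (i + 0.5) * s_out + shift, sampled from the input grid whose
// voxel j sits at (j + 0.5) * s_in. Border values are clamped.

static inline double sample_tri(const double* f, int nx, int ny, int nz,
                                double ux, double uy, double uz) {
  ux = std::min(std::max(ux, 0.0), (double)(nx - 1));
  uy = std::min(std::max(uy, 0.0), (double)(ny - 1));
  uz = std::min(std::max(uz, 0.0), (double)(nz - 1));
  int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy), z0 = (int)std::floor(uz);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = ux - x0, fy = uy - y0, fz = uz - z0;
  size_t nxy = (size_t)nx * ny;
  #define F(I,J,K) f[(size_t)(K) * nxy + (size_t)(J) * nx + (I)]
  double c00 = F(x0,y0,z0) * (1-fx) + F(x1,y0,z0) * fx;
  double c10 = F(x0,y1,z0) * (1-fx) + F(x1,y1,z0) * fx;
  double c01 = F(x0,y0,z1) * (1-fx) + F(x1,y0,z1) * fx;
  double c11 = F(x0,y1,z1) * (1-fx) + F(x1,y1,z1) * fx;
  #undef F
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector field, IntegerVector dim,
                           NumericVector spacing, IntegerVector out_dim,
                           NumericVector out_spacing, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const double* f = REAL(field);
  NumericVector res((size_t)ox * oy * oz);
  double* r = REAL(res);
  size_t nxy = (size_t)nx * ny;
  size_t k = 0;
  for (int zz = 0; zz < oz; zz++) {
    double uz = ((zz + 0.5) * out_spacing[2]) / spacing[2] - 0.5;
    for (int yy = 0; yy < oy; yy++) {
      double uy = ((yy + 0.5) * out_spacing[1]) / spacing[1] - 0.5;
      for (int xx = 0; xx < ox; xx++, k++) {
        double ux = ((xx + 0.5) * out_spacing[0]) / spacing[0] - 0.5;
        if (nearest) {
          int ix = (int)std::lround(std::min(std::max(ux, 0.0), (double)(nx-1)));
          int iy = (int)std::lround(std::min(std::max(uy, 0.0), (double)(ny-1)));
          int iz = (int)std::lround(std::min(std::max(uz, 0.0), (double)(nz-1)));
          r[k] = f[(size_t)iz * nxy + (size_t)iy * nx + ix];
        } else {
          r[k] = sample_tri(f, nx, ny, nz, ux, uy, uz);
        }
      }
    }
  }
  res.attr("dim") = out_dim;
  return res;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis with mirror (symmetric) padding.
// kernel has odd length; axis is 0, 1 or 2.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector field, IntegerVector dim,
                            NumericVector kernel, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int kl = kernel.size(), kh = kl / 2;
  const double* f = REAL(field);
  const double* w = REAL(kernel);
  NumericVector res(field.size());
  double* r = REAL(res);
  size_t nxy = (size_t)nx * ny;
  int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : nxy;

  // iterate over all lines along `axis`
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < n2; b++)
    for (int a = 0; a < n1; a++) {
      size_t base;
      if (axis == 0)      base = (size_t)b * nxy + (size_t)a * nx;
      else if (axis == 1) base = (size_t)b * nxy + a;
      else                base = (size_t)b * nx + a;
      for (int i = 0; i < nax; i++) {
        double acc = 0.0;
        for (int k = -kh; k <= kh; k++) {
          int j = i + k;
          if (j < 0) j = -j - 1;            // mirror
          else if (j >= nax) j = 2 * nax - j - 1;
          acc += w[k + kh] * f[base + (size_t)j * stride];
        }
        r[base + (size_t)i * stride] = acc;
      }
    }
  res.attr("dim") = dim;
  return res;
}

// ---------------------------------------------------------------------------
// Largest 26-connected foreground component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz, nxy = (size_t)nx * ny;
  const int* m = LOGICAL(mask);
  std::vector<int32_t> label(n, 0);
  int32_t cur = 0;
  size_t best_size = 0; int32_t best_label = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; s++) {
    if (!m[s] || label[s]) continue;
    cur++;
    size_t sz = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      size_t i = stack.back(); stack.pop_back();
      sz++;
      int xx = (int)(i % nx), yy = (int)((i / nx) % ny), zz = (int)(i / nxy);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int qx = xx + dx, qy = yy + dy, qz = zz + dz;
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            size_t q = (size_t)qz * nxy + (size_t)qy * nx + qx;
            if (m[q] && !label[q]) { label[q] = cur; stack.push_back(q); }
          }
    }
    if (sz > best_size) { best_size = sz; best_label = cur; }
  }
  LogicalVector res(n);
  int* r = LOGICAL(res);
  for (size_t i = 0; i < n; i++) r[i] = (label[i] == best_label && best_label);
  res.attr("dim") = dim;
  return res;
}
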