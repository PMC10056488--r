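// 3D volume primitives: separable Gaussian smoothing, scale-normalized
// Hessian eigenvalues for vesselness, 26-neighbour minimum-cost paths,
// distance to a polyline (tube rasterization / level-set seeding),
// narrow-band level-set evolution, connected components, and r=1 morphology.
#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline int refl(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

static void smooth_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (auto &x : k) x /= s;
  std::vector<double> out(v.size());
  int n[3] = {nx, ny, nz};
  long strides[3] = {1, (long)nx, (long)nx * ny};
  int na = n[axis];
  long sa = strides[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long idx = x + (long)nx * y + (long)nx * ny * z;
        int pos = (axis == 0) ? x : (axis == 1 ? y : z);
        double a = 0;
        for (int d = -rad; d <= rad; ++d) {
          int p = refl(pos + d, na);
          a += k[d + rad] * v[idx + (long)(p - pos) * sa];
        }
        out[idx] = a;
      }
  v.swap(out);
}

// [[Rcpp::export(name = ".cpp_gauss3d")]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims, NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int a = 0; a < 3; ++a) smooth_axis(v, nx, ny, nz, a, sigma_vox[a]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// analytic eigenvalues of a symmetric 3x3 matrix (ascending)
static void eig3(double a11, double a12, double a13, double a22, double a23,
                 double a33, double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
    std::sort(ev, ev + 3);
    return;
  }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11 / p, c12 = a12 / p, c13 = a13 / p;
  double c22 = b22 / p, c23 = a23 / p, c33 = b33 / p;
  double detB = c11 * (c22 * c33 - c23 * c23) - c12 * (c12 * c33 - c23 * c13) +
                c13 * (c12 * c23 - c22 * c13);
  double r = detB / 2.0;
  if (r < -1) r = -1;
  if (r > 1) r = 1;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  double e2 = 3.0 * q - e1 - e3;
  ev[0] = std::min(std::min(e1, e2), e3);
  ev[2] = std::max(std::max(e1, e2), e3);
  ev[1] = 3.0 * q - ev[0] - ev[2];
}

// Scale-normalized Hessian eigenvalues of a smoothed volume, sorted by
// increasing |lambda|. Spacing-aware central differences; multiplied by
// sigma_mm^2 for scale normalization.
// [[Rcpp::export(name = ".cpp_hessian_eig3d")]]
List cpp_hessian_eig3d(NumericVector vol, IntegerVector dims, NumericVector spacing,
                       double sigma_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  NumericVector l1(ntot), l2(ntot), l3(ntot);
  double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  double s2 = sigma_mm * sigma_mm;
  std::vector<double> v(vol.begin(), vol.end());
  std::vector<double> sg(3);
  sg[0] = sigma_mm / hx; sg[1] = sigma_mm / hy; sg[2] = sigma_mm / hz;
  for (int a = 0; a < 3; ++a) smooth_axis(v, nx, ny, nz, a, sg[a]);
  auto at = [&](int x, int y, int z) -> double {
    return v[refl(x, nx) + (long)nx * refl(y, ny) + (long)nx * ny * refl(z, nz)];
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long idx = x + (long)nx * y + (long)nx * ny * z;
        double c = at(x, y, z);
        double hxx = (at(x + 1, y, z) - 2 * c + at(x - 1, y, z)) / (hx * hx);
        double hyy = (at(x, y + 1, z) - 2 * c + at(x, y - 1, z)) / (hy * hy);
        double hzz = (at(x, y, z + 1) - 2 * c + at(x, y, z - 1)) / (hz * hz);
        double hxy = (at(x + 1, y + 1, z) - at(x + 1, y - 1, z) -
                      at(x - 1, y + 1, z) + at(x - 1, y - 1, z)) / (4 * hx * hy);
        double hxz = (at(x + 1, y, z + 1) - at(x + 1, y, z - 1) -
                      at(x - 1, y, z + 1) + at(x - 1, y, z - 1)) / (4 * hx * hz);
        double hyz = (at(x, y + 1, z + 1) - at(x, y + 1, z - 1) -
                      at(x, y - 1, z + 1) + at(x, y - 1, z - 1)) / (4 * hy * hz);
        double ev[3];
        eig3(s2 * hxx, s2 * hxy, s2 * hxz, s2 * hyy, s2 * hyz, s2 * hzz, ev);
        // sort by |lambda|
        double a0 = std::fabs(ev[0]), a1 = std::fabs(ev[1]), a2 = std::fabs(ev[2]);
        double o[3];
        if (a0 <= a1 && a0 <= a2) {
          o[0] = ev[0];
          if (a1 <= a2) { o[1] = ev[1]; o[2] = ev[2]; } else { o[1] = ev[2]; o[2] = ev[1]; }
        } else if (a1 <= a0 && a1 <= a2) {
          o[0] = ev[1];
          if (a0 <= a2) { o[1] = ev[0]; o[2] = ev[2]; } else { o[1] = ev[2]; o[2] = ev[0]; }
        } else {
          o[0] = ev[2];
          if (a0 <= a1) { o[1] = ev[0]; o[2] = ev[1]; } else { o[1] = ev[1]; o[2] = ev[0]; }
        }
        l1[idx] = o[0]; l2[idx] = o[1]; l3[idx] = o[2];
      }
  l1.attr("dim") = dims; l2.attr("dim") = dims; l3.attr("dim") = dims;
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}

// Minimum-cost path over the 26-neighbourhood. cost = per-voxel traversal
// cost; edge weight = physical step length * mean endpoint cost.
// start/end are 0-based voxel indices (x, y, z). Returns 0-based voxel path.
// [[Rcpp::export(name = ".cpp_dijkstra26")]]
IntegerMatrix cpp_dijkstra26(NumericVector cost, IntegerVector dims, NumericVector spacing,
                             IntegerVector start, IntegerVector end) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(ntot, INF);
  std::vector<long> prev(ntot, -1);
  std::vector<char> done(ntot, 0);
  long s = start[0] + (long)nx * start[1] + (long)nx * ny * start[2];
  long e = end[0] + (long)nx * end[1] + (long)nx * ny * end[2];
  typedef std::pair<double, long> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > heap;
  dist[s] = 0;
  heap.push(Node(0, s));
  // neighbour offsets
  std::vector<int> ox, oy, oz; std::vector<double> len;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        double lx = dx * spacing[0], ly = dy * spacing[1], lz = dz * spacing[2];
        len.push_back(std::sqrt(lx * lx + ly * ly + lz * lz));
      }
  while (!heap.empty()) {
    Node nd = heap.top(); heap.pop();
    long u = nd.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == e) break;
    int x = u % nx, y = (u / nx) % ny, z = u / ((long)nx * ny);
    for (size_t q = 0; q < ox.size(); ++q) {
      int xx = x + ox[q], yy = y + oy[q], zz = z + oz[q];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      long vtx = xx + (long)nx * yy + (long)nx * ny * zz;
      if (done[vtx]) continue;
      double w = dist[u] + len[q] * 0.5 * (cost[u] + cost[vtx]);
      if (w < dist[vtx]) {
        dist[vtx] = w;
        prev[vtx] = u;
        heap.push(Node(w, vtx));
      }
    }
  }
  if (!std::isfinite(dist[e])) stop("no finite-cost path between seeds");
  std::vector<long> path;
  for (long u = e; u != -1; u = prev[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  IntegerMatrix out(path.size(), 3);
  for (size_t q = 0; q < path.size(); ++q) {
    long u = path[q];
    out(q, 0) = u % nx;
    out(q, 1) = (u / nx) % ny;
    out(q, 2) = u / ((long)nx * ny);
  }
  return out;
}

// Distance (mm) from every voxel center to a polyline given in mm, plus the
// arclength (mm) of the nearest point on the polyline and a flag marking
// voxels whose nearest point is a clamped curve endpoint (beyond the flat
// end planes of the tube).
// [[Rcpp::export(name = ".cpp_tube_distance")]]
List cpp_tube_distance(IntegerVector dims, NumericVector spacing, NumericVector origin,
                       NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.nrow();
  long ntot = (long)nx * ny * nz;
  NumericVector dist(ntot), snear(ntot);
  LogicalVector clamped(ntot);
  std::vector<double> cum(np, 0.0);
  for (int k = 1; k < np; ++k) {
    double dx = pts(k, 0) - pts(k - 1, 0), dy = pts(k, 1) - pts(k - 1, 1),
           dz = pts(k, 2) - pts(k - 1, 2);
    cum[k] = cum[k - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  for (int z = 0; z < nz; ++z) {
    double pz = origin[2] + z * spacing[2];
    for (int y = 0; y < ny; ++y) {
      double py = origin[1] + y * spacing[1];
      for (int x = 0; x < nx; ++x) {
        double px = origin[0] + x * spacing[0];
        double best = std::numeric_limits<double>::infinity(), bs = 0;
        bool bcl = false;
        for (int k = 0; k + 1 < np; ++k) {
          double ax = pts(k, 0), ay = pts(k, 1), az = pts(k, 2);
          double bx = pts(k + 1, 0), by = pts(k + 1, 1), bz = pts(k + 1, 2);
          double ux = bx - ax, uy = by - ay, uz = bz - az;
          double L2 = ux * ux + uy * uy + uz * uz;
          double traw = 0;
          if (L2 > 0)
            traw = ((px - ax) * ux + (py - ay) * uy + (pz - az) * uz) / L2;
          double t = traw;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
          double qx = ax + t * ux - px, qy = ay + t * uy - py, qz = az + t * uz - pz;
          double d2 = qx * qx + qy * qy + qz * qz;
          if (d2 < best) {
            best = d2;
            bs = cum[k] + t * (cum[k + 1] - cum[k]);
            bcl = (k == 0 && traw < 0) || (k == np - 2 && traw > 1);
          }
        }
        long idx = x + (long)nx * y + (long)nx * ny * z;
        dist[idx] = std::sqrt(best);
        snear[idx] = bs;
        clamped[idx] = bcl;
      }
    }
  }
  dist.attr("dim") = dims; snear.attr("dim") = dims; clamped.attr("dim") = dims;
  return List::create(_["dist"] = dist, _["arclength"] = snear,
                      _["clamped"] = clamped);
}

// Narrow-band first-order upwind level-set evolution.
// phi < 0 inside; D = image force in [-1, 1] (positive expands);
// dphi/dt = -(D - kappa * meanCurvature) * |grad phi|.
// allowed == 0 freezes phi at +band (region cannot grow there).
// Convergence: relative change of the labeled volume < tol over `every` iters.
// [[Rcpp::export(name = ".cpp_levelset")]]
List cpp_levelset(NumericVector phi0, NumericVector D, IntegerVector dims,
                  LogicalVector allowed, double kappa, double dt, int max_iter,
                  double tol, int every, double band) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> nphi(ntot);
  long strideY = nx, strideZ = (long)nx * ny;
  auto clampband = [&](double v) {
    if (v > band) return band;
    if (v < -band) return -band;
    return v;
  };
  for (long i = 0; i < ntot; ++i) {
    phi[i] = clampband(phi[i]);
    if (!allowed[i] && phi[i] > 0) phi[i] = band;
  }
  long prev_vol = 0;
  for (long i = 0; i < ntot; ++i) if (phi[i] < 0) ++prev_vol;
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          long i = x + strideY * y + strideZ * z;
          double p = phi[i];
          if (std::fabs(p) >= band - 1e-9) { nphi[i] = p; continue; }
          if (!allowed[i]) { nphi[i] = band; continue; }
          double pxm = (x > 0) ? phi[i - 1] : p;
          double pxp = (x < nx - 1) ? phi[i + 1] : p;
          double pym = (y > 0) ? phi[i - strideY] : p;
          double pyp = (y < ny - 1) ? phi[i + strideY] : p;
          double pzm = (z > 0) ? phi[i - strideZ] : p;
          double pzp = (z < nz - 1) ? phi[i + strideZ] : p;
          double dxm = p - pxm, dxp = pxp - p;
          double dym = p - pym, dyp = pyp - p;
          double dzm = p - pzm, dzp = pzp - p;
          double F = D[i];
          // curvature from central differences
          double cx = 0.5 * (pxp - pxm), cy = 0.5 * (pyp - pym), cz = 0.5 * (pzp - pzm);
          double g2 = cx * cx + cy * cy + cz * cz;
          double curv = 0.0;
          if (g2 > 1e-12 && kappa != 0) {
            // second derivatives
            double pxx = pxp - 2 * p + pxm;
            double pyy = pyp - 2 * p + pym;
            double pzz = pzp - 2 * p + pzm;
            auto PHI = [&](int ddx, int ddy, int ddz) -> double {
              int xx = x + ddx, yy = y + ddy, zz = z + ddz;
              if (xx < 0) xx = 0; if (xx >= nx) xx = nx - 1;
              if (yy < 0) yy = 0; if (yy >= ny) yy = ny - 1;
              if (zz < 0) zz = 0; if (zz >= nz) zz = nz - 1;
              return phi[xx + strideY * yy + strideZ * zz];
            };
            double pxy = 0.25 * (PHI(1, 1, 0) - PHI(1, -1, 0) - PHI(-1, 1, 0) + PHI(-1, -1, 0));
            double pxz = 0.25 * (PHI(1, 0, 1) - PHI(1, 0, -1) - PHI(-1, 0, 1) + PHI(-1, 0, -1));
            double pyz = 0.25 * (PHI(0, 1, 1) - PHI(0, 1, -1) - PHI(0, -1, 1) + PHI(0, -1, -1));
            curv = (pxx * (cy * cy + cz * cz) + pyy * (cx * cx + cz * cz) +
                    pzz * (cx * cx + cy * cy) - 2 * (cx * cy * pxy + cx * cz * pxz + cy * cz * pyz)) /
                   (2.0 * std::pow(g2, 1.5) + 1e-12);
            // clamp curvature to grid scale
            if (curv > 1.0) curv = 1.0;
            if (curv < -1.0) curv = -1.0;
          }
          double Feff = F - kappa * curv;
          double gradP, dphi;
          if (Feff > 0) {
            gradP = std::sqrt(std::pow(std::max(dxm, 0.0), 2) + std::pow(std::min(dxp, 0.0), 2) +
                              std::pow(std::max(dym, 0.0), 2) + std::pow(std::min(dyp, 0.0), 2) +
                              std::pow(std::max(dzm, 0.0), 2) + std::pow(std::min(dzp, 0.0), 2));
            dphi = -dt * Feff * gradP;
          } else {
            gradP = std::sqrt(std::pow(std::min(dxm, 0.0), 2) + std::pow(std::max(dxp, 0.0), 2) +
                              std::pow(std::min(dym, 0.0), 2) + std::pow(std::max(dyp, 0.0), 2) +
                              std::pow(std::min(dzm, 0.0), 2) + std::pow(std::max(dzp, 0.0), 2));
            dphi = -dt * Feff * gradP;
          }
          nphi[i] = clampband(p + dphi);
        }
    phi.swap(nphi);
    if ((it + 1) % every == 0) {
      long vol = 0;
      for (long i = 0; i < ntot; ++i) if (phi[i] < 0) ++vol;
      double rel = std::fabs((double)vol - (double)prev_vol) /
                   std::max(1.0, (double)prev_vol);
      if (rel < tol) { converged = true; ++it; break; }
      prev_vol = vol;
    }
  }
  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = dims;
  return List::create(_["phi"] = out, _["converged"] = converged, _["iterations"] = it);
}

// 26-connected components of a logical mask; labels 1..K, 0 elsewhere.
// [[Rcpp::export(name = ".cpp_components26")]]
IntegerVector cpp_components26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  IntegerVector lab(ntot);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long u = stack.back(); stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / ((long)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            long v = xx + (long)nx * yy + (long)nx * ny * zz;
            if (mask[v] && !lab[v]) { lab[v] = next; stack.push_back(v); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 6-neighbour binary dilation (dilate = true) or erosion, radius 1
// [[Rcpp::export(name = ".cpp_morph3d")]]
LogicalVector cpp_morph3d(LogicalVector mask, IntegerVector dims, bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long ntot = (long)nx * ny * nz;
  LogicalVector out(ntot);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long i = x + (long)nx * y + (long)nx * ny * z;
        bool acc = mask[i];
        const int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
        for (int q = 0; q < 6; ++q) {
          int xx = x + offs[q][0], yy = y + offs[q][1], zz = z + offs[q][2];
          bool v;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            v = false;
          else
            v = mask[xx + (long)nx * yy + (long)nx * ny * zz];
          if (dilate) acc = acc || v; else acc = acc && v;
        }
        out[i] = acc;
      }
  out.attr("dim") = dims;
  return out;
}
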