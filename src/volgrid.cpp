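#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Linear index helpers: arrays are stored in R column-major order, 0-based here.
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Masked Pearson autocorrelation of a 3D (or 2D with nz = 1) volume at every
// integer-voxel lag. NA voxels (unvisited) are excluded pairwise; a lag with
// fewer than min_overlap contributing pairs is NA. The normalisation is the
// per-lag Pearson form, so r(0,0,0) = 1 and r(tau) = r(-tau).
// [[Rcpp::export]]
List cpp_autocorr(NumericVector vol, IntegerVector dims, int min_overlap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int lx = 2 * nx - 1, ly = 2 * ny - 1, lz = 2 * nz - 1;
  NumericVector r(lx * ly * lz, NA_REAL);
  IntegerVector m(lx * ly * lz, 0);
  const double *v = REAL(vol);

  for (int tz = -(nz - 1); tz <= nz - 1; ++tz) {
    for (int ty = -(ny - 1); ty <= ny - 1; ++ty) {
      for (int tx = -(nx - 1); tx <= nx - 1; ++tx) {
        // overlap ranges for a at (x,y,z) paired with b at (x-tx, y-ty, z-tz)
        int x0 = std::max(0, tx), x1 = std::min(nx - 1, nx - 1 + tx);
        int y0 = std::max(0, ty), y1 = std::min(ny - 1, ny - 1 + ty);
        int z0 = std::max(0, tz), z1 = std::min(nz - 1, nz - 1 + tz);
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        int cnt = 0;
        for (int z = z0; z <= z1; ++z) {
          for (int y = y0; y <= y1; ++y) {
            const double *pa = v + idx3(x0, y, z, nx, ny);
            const double *pb = v + idx3(x0 - tx, y - ty, z - tz, nx, ny);
            for (int x = x0; x <= x1; ++x, ++pa, ++pb) {
              double a = *pa, b = *pb;
              if (ISNAN(a) || ISNAN(b)) continue;
              sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
              ++cnt;
            }
          }
        }
        int out = idx3(tx + nx - 1, ty + ny - 1, tz + nz - 1, lx, ly);
        m[out] = cnt;
        if (cnt >= min_overlap) {
          double va = cnt * saa - sa * sa;
          double vb = cnt * sbb - sb * sb;
          if (va > 1e-12 && vb > 1e-12)
            r[out] = (cnt * sab - sa * sb) / std::sqrt(va * vb);
        }
      }
    }
  }
  return List::create(_["r"] = r, _["m"] = m);
}

// Connected-component labelling of a logical mask. connectivity 6 or 26 in 3D;
// with nz = 1 connectivity 26 reduces to 2D 8-connectivity and 6 to 4.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) > 1)
              continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
            int j = idx3(x, y, z, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
    }
  }
  return lab;
}

// Trilinear interpolation of a 3D volume at arbitrary (1-based, voxel-centre)
// coordinates. Points outside the volume, or touching an NA corner, give NA.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dims,
                          NumericVector xi, NumericVector yi, NumericVector zi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = xi.size();
  NumericVector out(np, NA_REAL);
  const double *v = REAL(vol);
  for (int i = 0; i < np; ++i) {
    double x = xi[i] - 1.0, y = yi[i] - 1.0, z = zi[i] - 1.0;
    if (ISNAN(x) || ISNAN(y) || ISNAN(z)) continue;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) continue;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1 && nx > 1) --x0;
    if (y0 == ny - 1 && ny > 1) --y0;
    if (z0 == nz - 1 && nz > 1) --z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0;
    bool bad = false;
    for (int cz = 0; cz <= 1 && !bad; ++cz) {
      for (int cy = 0; cy <= 1 && !bad; ++cy) {
        for (int cx = 0; cx <= 1 && !bad; ++cx) {
          double w = (cx ? fx : 1 - fx) * (cy ? fy : 1 - fy) * (cz ? fz : 1 - fz);
          if (w == 0) continue;
          double val = v[idx3(cx ? x1 : x0, cy ? y1 : y0, cz ? z1 : z0, nx, ny)];
          if (ISNAN(val)) { bad = true; break; }
          acc += w * val;
        }
      }
    }
    if (!bad) out[i] = acc;
  }
  return out;
}

// Adaptive-binning rate estimation on pre-binned occupancy-sample and spike
// counts. For each voxel a sphere (voxel-centre distance) is expanded in
// 1-voxel steps until r > alpha / (n * sqrt(s)) with s >= 1; the rate is then
// (s / n) * rate_hz. If the sphere reaches max_r with no spike inside, the
// rate is 0; if the criterion is never met otherwise, NA.
// [[Rcpp::export]]
List cpp_adaptive(NumericVector occ, NumericVector spk, IntegerVector dims,
                  double alpha, int max_r, double rate_hz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector rate(n, NA_REAL);
  NumericVector radius(n, NA_REAL);

  // offsets grouped by integer radius step
  std::vector< std::vector<int> > odx(max_r + 1), ody(max_r + 1), odz(max_r + 1);
  int zr = (nz == 1) ? 0 : max_r;
  for (int dz = -zr; dz <= zr; ++dz)
    for (int dy = -max_r; dy <= max_r; ++dy)
      for (int dx = -max_r; dx <= max_r; ++dx) {
        double d = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        if (d > max_r) continue;
        int g = (int)std::ceil(d);
        if (g == 0) g = 0;
        odx[g].push_back(dx); ody[g].push_back(dy); odz[g].push_back(dz);
      }

  const double *po = REAL(occ), *ps = REAL(spk);
  for (int cz = 0; cz < nz; ++cz) {
    for (int cy = 0; cy < ny; ++cy) {
      for (int cx = 0; cx < nx; ++cx) {
        double nacc = 0, sacc = 0;
        double got = NA_REAL;
        for (int r = 0; r <= max_r; ++r) {
          for (size_t k = 0; k < odx[r].size(); ++k) {
            int x = cx + odx[r][k], y = cy + ody[r][k], z = cz + odz[r][k];
            if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
            int j = idx3(x, y, z, nx, ny);
            nacc += po[j]; sacc += ps[j];
          }
          if (r >= 1 && sacc >= 1 && nacc > 0 &&
              (double)r > alpha / (nacc * std::sqrt(sacc))) {
            got = (sacc / nacc) * rate_hz;
            radius[idx3(cx, cy, cz, nx, ny)] = r;
            break;
          }
        }
        int c = idx3(cx, cy, cz, nx, ny);
        if (!ISNAN(got)) rate[c] = got;
        else if (sacc < 1) rate[c] = 0.0;  // no spikes reachable at all
      }
    }
  }
  return List::create(_["rate"] = rate, _["radius"] = radius);
}

// Squared Euclidean distance transform (distance to nearest TRUE voxel),
// Felzenszwalb & Huttenlocher separable lower-envelope algorithm.
static void edt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  double *o = REAL(out);
  const double BIG = 1e18;
  for (int i = 0; i < nx * ny * nz; ++i) o[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = o[idx3(x, y, z, nx, ny)];
      edt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) o[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = o[idx3(x, y, z, nx, ny)];
      edt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) o[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  if (nz > 1)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = o[idx3(x, y, z, nx, ny)];
        edt1d(f, d, nz);
        for (int z = 0; z < nz; ++z) o[idx3(x, y, z, nx, ny)] = d[z];
      }
  return out;
}

// Field-shuffle mover. Given the source rate map (NA = unvisited), a watershed
// field label per visited voxel, each field's peak voxel and a new random peak
// position, bins are moved one per field per round (fields cycled in order)
// from the source to an empty copy: each bin goes to its ideal
// offset-from-peak position, or failing that to the nearest free visited
// position in city-block distance (deterministic raster scan within a shell).
// [[Rcpp::export]]
NumericVector cpp_field_shuffle(NumericVector rate, IntegerVector dims,
                                List field_bins, IntegerVector old_peaks,
                                IntegerVector new_peaks) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int nf = field_bins.size();
  NumericVector out(n, NA_REAL);
  std::vector<bool> valid(n), occupied(n, false);
  for (int i = 0; i < n; ++i) valid[i] = !ISNAN(rate[i]);

  // place peaks first
  for (int f = 0; f < nf; ++f) {
    int np = new_peaks[f] - 1;
    out[np] = rate[old_peaks[f] - 1];
    occupied[np] = true;
  }

  std::vector< std::vector<int> > bins(nf);
  std::vector<size_t> pos(nf, 0);
  for (int f = 0; f < nf; ++f) {
    IntegerVector b = field_bins[f];
    bins[f].assign(b.begin(), b.end());
  }

  bool any = true;
  int maxshell = 2 * (nx + ny + nz) + 3;
  while (any) {
    any = false;
    for (int f = 0; f < nf; ++f) {
      if (pos[f] >= bins[f].size()) continue;
      any = true;
      int bin = bins[f][pos[f]++] - 1;
      int op = old_peaks[f] - 1, np = new_peaks[f] - 1;
      int bx = bin % nx, by = (bin / nx) % ny, bz = bin / (nx * ny);
      int ox = op % nx, oy = (op / nx) % ny, oz = op / (nx * ny);
      int nxp = np % nx, nyp = (np / nx) % ny, nzp = np / (nx * ny);
      int ix = nxp + (bx - ox), iy = nyp + (by - oy), iz = nzp + (bz - oz);
      int target = -1;
      for (int shell = 0; shell <= maxshell && target < 0; ++shell) {
        for (int dz = -shell; dz <= shell && target < 0; ++dz) {
          int rem = shell - std::abs(dz);
          for (int dy = -rem; dy <= rem && target < 0; ++dy) {
            int adx = rem - std::abs(dy);
            for (int sgn = 0; sgn < (adx == 0 ? 1 : 2) && target < 0; ++sgn) {
              int dx = sgn == 0 ? adx : -adx;
              int x = ix + dx, y = iy + dy, z = iz + dz;
              if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                continue;
              int j = idx3(x, y, z, nx, ny);
              if (valid[j] && !occupied[j]) target = j;
            }
          }
        }
      }
      if (target >= 0) { out[target] = rate[bin]; occupied[target] = true; }
    }
  }
  return out;
}

// Counts of spike-pair lags for a spike-train autocorrelogram: pairs (i, j),
// i != j, with |t_j - t_i| <= window, binned symmetrically around zero lag.
// [[Rcpp::export]]
NumericVector cpp_spike_xcorr(NumericVector times, double window, double binw) {
  int nb = 2 * (int)std::round(window / binw) + 1;
  int half = nb / 2;
  NumericVector counts(nb, 0.0);
  int n = times.size();
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double lag = times[j] - times[i];
      if (lag > window) break;
      int b = (int)std::round(lag / binw);
      counts[half + b] += 1.0;
      counts[half - b] += 1.0;
    }
  }
  return counts;
}

// Fast hexagonal/square gridness scoring of one 2D autocorrelogram slice
// (NA allowed). Mirrors the R reference implementation grid_score():
// threshold > thr, 8-connected components, 7 most central centroids, annulus
// = ring +/- central radius, Pearson correlation against rotated copies
// (bilinear sampling), HGS = min(60,120) - max(30,90,150),
// SGS = min(90,180) - max(45,135,225).
// [[Rcpp::export]]
NumericVector cpp_score_slice(NumericVector a, int nx, int ny, double thr,
                              int min_pixels) {
  NumericVector out = NumericVector::create(NA_REAL, NA_REAL);
  const int n = nx * ny;
  std::vector<int> lab(n, 0);
  int ncomp = 0;
  {
    std::vector<int> stack;
    for (int i = 0; i < n; ++i) {
      if (lab[i] || ISNAN(a[i]) || a[i] <= thr) continue;
      lab[i] = ++ncomp;
      stack.push_back(i);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int cx = cur % nx, cy = cur / nx;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy) continue;
            int x = cx + dx, y = cy + dy;
            if (x < 0 || x >= nx || y < 0 || y >= ny) continue;
            int j = x + nx * y;
            if (!lab[j] && !ISNAN(a[j]) && a[j] > thr) {
              lab[j] = ncomp; stack.push_back(j);
            }
          }
      }
    }
  }
  if (ncomp < 7) return out;
  std::vector<double> sx(ncomp, 0), sy(ncomp, 0), cnt(ncomp, 0);
  for (int i = 0; i < n; ++i) {
    if (!lab[i]) continue;
    int c = lab[i] - 1;
    sx[c] += (i % nx) + 1;
    sy[c] += (i / nx) + 1;
    cnt[c] += 1;
  }
  double cx0 = (nx + 1) / 2.0, cy0 = (ny + 1) / 2.0;
  std::vector< std::pair<double, int> > dist(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    double dx = sx[c] / cnt[c] - cx0, dy = sy[c] / cnt[c] - cy0;
    dist[c] = std::make_pair(std::sqrt(dx * dx + dy * dy), c);
  }
  std::partial_sort(dist.begin(), dist.begin() + 7, dist.end());
  int central = dist[0].second;
  double r_central = std::sqrt(cnt[central] / M_PI);
  double ring = 0;
  for (int k = 1; k < 7; ++k) ring += dist[k].first;
  ring /= 6.0;
  double inner = std::max(0.0, ring - r_central), outer = ring + r_central;

  std::vector<int> ann;
  ann.reserve(512);
  for (int i = 0; i < n; ++i) {
    if (ISNAN(a[i])) continue;
    double dx = (i % nx) + 1 - cx0, dy = (i / nx) + 1 - cy0;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d >= inner && d <= outer) ann.push_back(i);
  }
  if ((int)ann.size() < min_pixels) return out;

  const double angles[9] = {30, 45, 60, 90, 120, 135, 150, 180, 225};
  double rc[9];
  for (int k = 0; k < 9; ++k) {
    double th = angles[k] * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    int m = 0;
    for (size_t q = 0; q < ann.size(); ++q) {
      int i = ann[q];
      double ax = (i % nx) + 1 - cx0, ay = (i / nx) + 1 - cy0;
      double rx = ct * ax - st * ay + cx0, ry = st * ax + ct * ay + cy0;
      // bilinear sample at (rx, ry), 1-based
      double x = rx - 1, y = ry - 1;
      if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) continue;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      if (x0 == nx - 1 && nx > 1) --x0;
      if (y0 == ny - 1 && ny > 1) --y0;
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
      double fx = x - x0, fy = y - y0;
      double v00 = a[x0 + nx * y0], v10 = a[x1 + nx * y0];
      double v01 = a[x0 + nx * y1], v11 = a[x1 + nx * y1];
      double acc = 0;
      bool bad = false;
      double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
             w01 = (1 - fx) * fy, w11 = fx * fy;
      if (w00 > 0) { if (ISNAN(v00)) bad = true; else acc += w00 * v00; }
      if (!bad && w10 > 0) { if (ISNAN(v10)) bad = true; else acc += w10 * v10; }
      if (!bad && w01 > 0) { if (ISNAN(v01)) bad = true; else acc += w01 * v01; }
      if (!bad && w11 > 0) { if (ISNAN(v11)) bad = true; else acc += w11 * v11; }
      if (bad) continue;
      double b0 = a[i];
      sa += b0; sb += acc; saa += b0 * b0; sbb += acc * acc; sab += b0 * acc;
      ++m;
    }
    if (m < min_pixels) { rc[k] = NA_REAL; continue; }
    double va = m * saa - sa * sa, vb = m * sbb - sb * sb;
    rc[k] = (va > 1e-12 * m && vb > 1e-12 * m)
      ? (m * sab - sa * sb) / std::sqrt(va * vb) : NA_REAL;
  }
  // indices: 0:30 1:45 2:60 3:90 4:120 5:135 6:150 7:180 8:225
  double hgs = std::min(rc[2], rc[4]) -
    std::max(rc[0], std::max(rc[3], rc[6]));
  double sgs = std::min(rc[3], rc[7]) -
    std::max(rc[1], std::max(rc[5], rc[8]));
  out[0] = hgs;
  out[1] = sgs;
  return out;
}

// Full plane-sampling loop: extract the central oblique slice for every
// (pitch, azimuth) normal and score it with cpp_score_slice's logic.
// Returns hgs and sgs as n_pitch x n_azimuth matrices (column-major).
// [[Rcpp::export]]
List cpp_sample_planes(NumericVector vol, IntegerVector dims,
                       NumericVector pitches, NumericVector azimuths,
                       double thr, int min_pixels) {
  const int np = pitches.size(), na = azimuths.size();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int side = 2 * (int)std::ceil(std::sqrt(3.0) * std::max(nx, std::max(ny, nz)) / 2.0) + 1;
  NumericMatrix hgs(np, na), sgs(np, na);
  std::fill(hgs.begin(), hgs.end(), NA_REAL);
  std::fill(sgs.begin(), sgs.end(), NA_REAL);
  NumericVector slice(side * side);
  double cx = (nx + 1) / 2.0, cy = (ny + 1) / 2.0, cz = (nz + 1) / 2.0;
  const double *v = REAL(vol);

  for (int ip = 0; ip < np; ++ip) {
    for (int ia = 0; ia < na; ++ia) {
      double p = pitches[ip] * M_PI / 180.0, az = azimuths[ia] * M_PI / 180.0;
      double nrm[3] = {std::sin(p) * std::cos(az), std::sin(p) * std::sin(az),
                       std::cos(p)};
      double e1[3], e2[3];
      if (std::fabs(nrm[2]) > 1 - 1e-9) {
        e1[0] = 1; e1[1] = 0; e1[2] = 0;
      } else {
        double nl = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1]);
        e1[0] = -nrm[1] / nl; e1[1] = nrm[0] / nl; e1[2] = 0;
      }
      e2[0] = nrm[1] * e1[2] - nrm[2] * e1[1];
      e2[1] = nrm[2] * e1[0] - nrm[0] * e1[2];
      e2[2] = nrm[0] * e1[1] - nrm[1] * e1[0];
      // sample slice
      for (int jv = 0; jv < side; ++jv) {
        double ov = jv + 1 - (side + 1) / 2.0;
        for (int ju = 0; ju < side; ++ju) {
          double ou = ju + 1 - (side + 1) / 2.0;
          double x = cx + ou * e1[0] + ov * e2[0] - 1.0;
          double y = cy + ou * e1[1] + ov * e2[1] - 1.0;
          double z = cz + ou * e1[2] + ov * e2[2] - 1.0;
          double val = NA_REAL;
          if (x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 &&
              z <= nz - 1) {
            int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                z0 = (int)std::floor(z);
            if (x0 == nx - 1 && nx > 1) --x0;
            if (y0 == ny - 1 && ny > 1) --y0;
            if (z0 == nz - 1 && nz > 1) --z0;
            int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                z1 = std::min(z0 + 1, nz - 1);
            double fx = x - x0, fy = y - y0, fz = z - z0;
            double acc = 0;
            bool bad = false;
            for (int ccz = 0; ccz <= 1 && !bad; ++ccz)
              for (int ccy = 0; ccy <= 1 && !bad; ++ccy)
                for (int ccx = 0; ccx <= 1 && !bad; ++ccx) {
                  double wgt = (ccx ? fx : 1 - fx) * (ccy ? fy : 1 - fy) *
                    (ccz ? fz : 1 - fz);
                  if (wgt == 0) continue;
                  double vv = v[idx3(ccx ? x1 : x0, ccy ? y1 : y0,
                                     ccz ? z1 : z0, nx, ny)];
                  if (ISNAN(vv)) { bad = true; break; }
                  acc += wgt * vv;
                }
            if (!bad) val = acc;
          }
          slice[ju + side * jv] = val;
        }
      }
      NumericVector sc = cpp_score_slice(slice, side, side, thr, min_pixels);
      hgs(ip, ia) = sc[0];
      sgs(ip, ia) = sc[1];
      if (pitches[ip] == 0) {  // horizontal plane shared by all azimuths
        for (int k = 0; k < na; ++k) { hgs(ip, k) = sc[0]; sgs(ip, k) = sc[1]; }
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["hgs"] = hgs, _["sgs"] = sgs);
}
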