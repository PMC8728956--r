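// Monte Carlo photon transport kernel on a voxel grid.
//
// Geometry convention: continuous positions in grid units; voxel (i,j,k)
// spans the half-open box [i,i+1)x[j,j+1)x[k,k+1), 0-based indices.
// Optical coefficients arrive per mm and are converted to per-grid-unit
// internally via unitinmm. Label 0 is the background/outside medium: a
// photon stepping into a 0-labelled voxel escapes the domain there.
//
// RNG: per-photon substreams. A photon's stream key is derived from
// (global seed, worker id, photon index) with a splitmix64-style mixer;
// the stream itself is xorshift128+. A detected photon stores its 64-bit
// key (two 32-bit halves), so replay re-simulates the identical
// trajectory from the key alone.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double C0_MM_S = 2.99792458e11; // vacuum speed of light, mm/s
static const double INF = std::numeric_limits<double>::infinity();

// ------------------------------------------------------------------ RNG ----

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s0, s1;
  void seed(uint64_t key) {
    s0 = mix64(key);
    s1 = mix64(key ^ 0xA5A5A5A55A5A5A5AULL);
    if (!(s0 | s1)) s1 = 0x1ULL;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in (0, 1]
  inline double unif() {
    return ((next() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

static inline uint64_t worker_key(int seed, int worker) {
  return mix64((uint64_t)(uint32_t)seed * 0xD1B54A32D192ED03ULL +
               (uint64_t)(uint32_t)worker);
}

static inline uint64_t photon_key(uint64_t wkey, uint64_t i) {
  return mix64(wkey + i * 0x9E3779B97F4A7C15ULL);
}

// -------------------------------------------------------------- physics ----

// 1 - exp(-x) for x >= 0; series branch keeps the hot path cheap for the
// tiny per-segment optical depths, relative error < 1e-10 at the switch
static inline double one_minus_exp_neg(double x) {
  if (x < 0.01)
    return x * (1.0 - x * (0.5 - x * (1.0 / 6.0 - x * (1.0 / 24.0))));
  return 1.0 - std::exp(-x);
}

// unpolarized Fresnel reflectance; returns 1 beyond the critical angle
static inline double fresnel_R(double cosi, double n1, double n2) {
  if (n1 == n2) return 0.0;
  double eta = n1 / n2;
  double sint2 = eta * eta * (1.0 - cosi * cosi);
  if (sint2 >= 1.0) return 1.0;
  double cost = std::sqrt(1.0 - sint2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine; g = 0 falls back to isotropic
static inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

static inline void fast_sincos(double x, double* s, double* c) {
#if defined(__GNUC__) && defined(__linux__)
  sincos(x, s, c);
#else
  *s = std::sin(x); *c = std::cos(x);
#endif
}

// scattering rotation on the hot path: the azimuth unit vector is drawn
// by rejection from the unit disk (double-angle trick) instead of
// sin/cos, and renormalization is first order (per-event error O(1e-32),
// far below the drift any trajectory can accumulate)
static inline void scatter_dir(double* d, double ct, Stream& R) {
  double cp, sp;
  for (;;) {
    double x = 2.0 * R.unif() - 1.0, y = 2.0 * R.unif() - 1.0;
    double r2 = x * x + y * y;
    if (r2 <= 1.0 && r2 > 1e-12) {
      double ir2 = 1.0 / r2;
      cp = (x * x - y * y) * ir2;
      sp = 2.0 * x * y * ir2;
      break;
    }
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  if (std::fabs(d[2]) > 0.9999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (d[2] > 0 ? 1.0 : -1.0);
  } else {
    double x = d[0], y = d[1], z = d[2];
    double den2 = 1.0 - z * z;
    double iden = 1.0 / std::sqrt(den2);
    d[0] = st * (x * z * cp - y * sp) * iden + x * ct;
    d[1] = st * (y * z * cp + x * sp) * iden + y * ct;
    d[2] = -st * cp / iden + z * ct;
  }
  double nn2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  double corr = 1.5 - 0.5 * nn2;
  d[0] *= corr; d[1] *= corr; d[2] *= corr;
}

// rotate unit vector d by polar cosine ct and azimuth phi about itself
static inline void rotate_dir(double* d, double ct, double phi) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp, sp;
  fast_sincos(phi, &sp, &cp);
  if (std::fabs(d[2]) > 0.9999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (d[2] > 0 ? 1.0 : -1.0);
  } else {
    double x = d[0], y = d[1], z = d[2];
    double den = std::sqrt(1.0 - z * z);
    d[0] = st * (x * z * cp - y * sp) / den + x * ct;
    d[1] = st * (y * z * cp + x * sp) / den + y * ct;
    d[2] = -st * cp * den + z * ct;
  }
  double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nn; d[1] /= nn; d[2] /= nn;
}

// --------------------------------------------------------------- source ----

// type codes (kept in step with R-side source_type_code())
enum SrcType { SRC_PENCIL = 0, SRC_ISOTROPIC, SRC_CONE, SRC_GAUSSIAN,
               SRC_PLANAR, SRC_PATTERN, SRC_FOURIER, SRC_DISK,
               SRC_LINE, SRC_SLIT, SRC_PATTERN3D };

struct Source {
  int type;
  double pos[3], dir[3], p1[4], p2[4], focus;
  std::vector<double> pattern;
  int pdim[3];
  double u1[3], u2[3]; // orthonormal frame perpendicular to dir
};

static void build_frame(Source& S) {
  const double* d = S.dir;
  double a[3] = {1.0, 0.0, 0.0};
  if (std::fabs(d[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
  // u1 = normalize(a x d), u2 = d x u1
  S.u1[0] = a[1] * d[2] - a[2] * d[1];
  S.u1[1] = a[2] * d[0] - a[0] * d[2];
  S.u1[2] = a[0] * d[1] - a[1] * d[0];
  double nn = std::sqrt(S.u1[0]*S.u1[0] + S.u1[1]*S.u1[1] + S.u1[2]*S.u1[2]);
  for (int k = 0; k < 3; k++) S.u1[k] /= nn;
  S.u2[0] = d[1] * S.u1[2] - d[2] * S.u1[1];
  S.u2[1] = d[2] * S.u1[0] - d[0] * S.u1[2];
  S.u2[2] = d[0] * S.u1[1] - d[1] * S.u1[0];
}

static Source parse_source(List src) {
  Source S;
  S.type = as<int>(src["type"]);
  NumericVector pos = src["pos"], dir = src["dir"];
  NumericVector p1 = src["param1"], p2 = src["param2"];
  for (int k = 0; k < 3; k++) { S.pos[k] = pos[k]; S.dir[k] = dir[k]; }
  for (int k = 0; k < 4; k++) { S.p1[k] = p1[k]; S.p2[k] = p2[k]; }
  S.focus = as<double>(src["focus"]);
  S.pdim[0] = S.pdim[1] = S.pdim[2] = 1;
  if (src.containsElementNamed("pattern") && !Rf_isNull(src["pattern"])) {
    NumericVector pat = src["pattern"];
    S.pattern.assign(pat.begin(), pat.end());
    IntegerVector pd = src["pattern_dim"];
    for (int k = 0; k < pd.size() && k < 3; k++) S.pdim[k] = pd[k];
  }
  build_frame(S);
  return S;
}

static inline bool src_is_area(int type) {
  return type == SRC_GAUSSIAN || type == SRC_PLANAR || type == SRC_PATTERN ||
         type == SRC_FOURIER || type == SRC_DISK || type == SRC_LINE ||
         type == SRC_SLIT || type == SRC_PATTERN3D;
}

// Draw launch position/direction/weight. Draw order per type is fixed; a
// photon's trajectory is a pure function of its stream key.
static inline void launch(const Source& S, Stream& R,
                          double* pos, double* dir, double& w) {
  for (int k = 0; k < 3; k++) { pos[k] = S.pos[k]; dir[k] = S.dir[k]; }
  w = 1.0;
  switch (S.type) {
  case SRC_PENCIL:
    break;
  case SRC_ISOTROPIC: {
    double ct = 2.0 * R.unif() - 1.0;
    double phi = 2.0 * M_PI * R.unif();
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    dir[0] = st * std::cos(phi); dir[1] = st * std::sin(phi); dir[2] = ct;
    break;
  }
  case SRC_CONE: {
    double ctmax = std::cos(S.p1[0]);
    double ct = 1.0 - R.unif() * (1.0 - ctmax); // uniform solid angle
    double phi = 2.0 * M_PI * R.unif();
    rotate_dir(dir, ct, phi);
    break;
  }
  case SRC_GAUSSIAN: {
    // intensity ~ exp(-r^2 / w0^2), w0 = param1[0]
    double r = S.p1[0] * std::sqrt(-std::log(R.unif()));
    double phi = 2.0 * M_PI * R.unif();
    double c = std::cos(phi), s = std::sin(phi);
    for (int k = 0; k < 3; k++) pos[k] += r * (c * S.u1[k] + s * S.u2[k]);
    break;
  }
  case SRC_PLANAR: case SRC_PATTERN: case SRC_FOURIER: {
    double u = 1.0 - R.unif(), v = 1.0 - R.unif(); // [0, 1)
    for (int k = 0; k < 3; k++) pos[k] += u * S.p1[k] + v * S.p2[k];
    if (S.type == SRC_PATTERN) {
      int ix = std::min((int)(u * S.pdim[0]), S.pdim[0] - 1);
      int iy = std::min((int)(v * S.pdim[1]), S.pdim[1] - 1);
      w = S.pattern[ix + (size_t)S.pdim[0] * iy];
    } else if (S.type == SRC_FOURIER) {
      // param1[3] = kx + phase/(2*pi) fractional packing; param2[3] = ky
      double kx = std::floor(S.p1[3]);
      double phi0 = (S.p1[3] - kx) * 2.0 * M_PI;
      double ky = std::floor(S.p2[3]);
      w = 0.5 * (1.0 + std::cos(2.0 * M_PI * (kx * u + ky * v) + phi0));
    }
    break;
  }
  case SRC_DISK: {
    double r = S.p1[0] * std::sqrt(R.unif());
    double phi = 2.0 * M_PI * R.unif();
    double c = std::cos(phi), s = std::sin(phi);
    for (int k = 0; k < 3; k++) pos[k] += r * (c * S.u1[k] + s * S.u2[k]);
    break;
  }
  case SRC_LINE: case SRC_SLIT: {
    double u = 1.0 - R.unif();
    for (int k = 0; k < 3; k++) pos[k] += u * S.p1[k];
    break;
  }
  case SRC_PATTERN3D: {
    double u = 1.0 - R.unif(), v = 1.0 - R.unif(), s = 1.0 - R.unif();
    pos[0] += u * S.p1[0]; pos[1] += v * S.p1[1]; pos[2] += s * S.p1[2];
    int ix = std::min((int)(u * S.pdim[0]), S.pdim[0] - 1);
    int iy = std::min((int)(v * S.pdim[1]), S.pdim[1] - 1);
    int iz = std::min((int)(s * S.pdim[2]), S.pdim[2] - 1);
    w = S.pattern[ix + (size_t)S.pdim[0] * (iy + (size_t)S.pdim[1] * iz)];
    break;
  }
  }
  // focal-length redirection for area sources: focus > 0 convergent
  // (toward the focal point), focus < 0 divergent (away from the virtual
  // point behind the patch), infinite = collimated.
  if (src_is_area(S.type) && R_FINITE(S.focus) && S.focus != 0.0) {
    double ctr[3];
    for (int k = 0; k < 3; k++) ctr[k] = S.pos[k];
    if (S.type == SRC_PLANAR || S.type == SRC_PATTERN || S.type == SRC_FOURIER)
      for (int k = 0; k < 3; k++) ctr[k] += 0.5 * (S.p1[k] + S.p2[k]);
    else if (S.type == SRC_LINE || S.type == SRC_SLIT)
      for (int k = 0; k < 3; k++) ctr[k] += 0.5 * S.p1[k];
    else if (S.type == SRC_PATTERN3D)
      for (int k = 0; k < 3; k++) ctr[k] += 0.5 * S.p1[k];
    double f[3], nn = 0.0;
    for (int k = 0; k < 3; k++) {
      f[k] = ctr[k] + S.focus * S.dir[k] - pos[k];
      nn += f[k] * f[k];
    }
    nn = std::sqrt(nn);
    if (nn > 1e-12) {
      double sgn = S.focus > 0 ? 1.0 : -1.0;
      for (int k = 0; k < 3; k++) dir[k] = sgn * f[k] / nn;
    }
  }
}

// --------------------------------------------------------------- kernel ----

struct Grid {
  const int* lab;      // label volume (media_format 0)
  const double* fvol;  // interleaved per-voxel (mua, mus) per mm (format 1)
  int fmt, nx, ny, nz;
  size_t nvox;
  double unit;
  // per-label, per-grid-unit coefficients
  std::vector<double> mua, mus, g, n, tpu; // tpu = seconds per grid unit
  std::vector<double> imus, itpu;          // reciprocals for the hot loop
};

enum BC { BC_ABSORB = 0, BC_FRESNEL, BC_MIRROR, BC_CYCLIC };

struct RunAccum {
  double absorbed = 0, escaped = 0, expired = 0, rrnet = 0, launched = 0;
  std::vector<double> detp;   // row-major detected rows
  size_t ndetcol = 0, ndet = 0;
};

// slab-method entry into [0,nx]x[0,ny]x[0,nz]; returns entry axis or -1
static inline int enter_box(const Grid& G, double* pos, const double* dir) {
  double lim[3] = {(double)G.nx, (double)G.ny, (double)G.nz};
  bool inside = true;
  for (int k = 0; k < 3; k++)
    if (pos[k] < 0 || pos[k] >= lim[k]) inside = false;
  if (inside) return 3; // already inside, no face crossed
  double tn = -INF, tf = INF;
  int axis = -1;
  for (int k = 0; k < 3; k++) {
    if (dir[k] == 0.0) {
      if (pos[k] < 0 || pos[k] >= lim[k]) return -1;
    } else {
      double t1 = (0.0 - pos[k]) / dir[k];
      double t2 = (lim[k] - pos[k]) / dir[k];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tn) { tn = t1; axis = k; }
      if (t2 < tf) tf = t2;
    }
  }
  if (tn > tf || tf < 0 || tn < 0) return -1;
  for (int k = 0; k < 3; k++) pos[k] += dir[k] * (tn + 1e-9);
  for (int k = 0; k < 3; k++) {
    if (pos[k] < 0) pos[k] = 0;
    if (pos[k] >= lim[k]) pos[k] = lim[k] * (1.0 - 1e-15);
  }
  return axis;
}

// transport a single photon; deposits into flu (forward) and jac (replay)
static void transport(const Grid& G, const Source& S, uint64_t pkey,
                      double t0, double t1, double dt, int ngate,
                      const double* det, int ndetector,
                      const int* bc, bool mismatch,
                      double rr_thresh, double rr_p,
                      double* flu, int* nev, RunAccum& A,
                      int mode, double replay_w, double* jac,
                      double* out_pathsum) {
  Stream R;
  R.seed(pkey);
  double pos[3], dir[3], w, w0;
  launch(S, R, pos, dir, w);
  w0 = w;
  A.launched += w0;
  if (w <= 0) return;

  int M = (int)G.mua.size() - 1; // media labels 1..M
  std::vector<double> ppath(M, 0.0);
  std::vector<int> pscat(M, 0);
  double mom = 0.0, t = 0.0, pathsum = 0.0;

  // move to the domain if launched outside; apply specular transmission
  // at entry under refractive-index mismatch handling
  int entry = enter_box(G, pos, dir);
  if (entry < 0) { A.escaped += w; return; }
  int iv[3] = {(int)std::floor(pos[0]), (int)std::floor(pos[1]),
               (int)std::floor(pos[2])};
  int lims[3] = {G.nx, G.ny, G.nz};
  for (int k = 0; k < 3; k++) {
    if (iv[k] < 0) iv[k] = 0;
    if (iv[k] >= lims[k]) iv[k] = lims[k] - 1;
  }
  if (entry >= 0 && entry < 3 && mismatch) {
    size_t idx0 = (size_t)iv[0] + (size_t)G.nx * (iv[1] + (size_t)G.ny * iv[2]);
    int lb = G.fmt == 0 ? G.lab[idx0] : 1;
    double n1 = G.n[0], n2 = G.n[lb > 0 ? lb : 0];
    if (n1 != n2 && lb > 0) {
      double cosi = std::fabs(dir[entry]);
      double eta = n1 / n2;
      double sint2 = eta * eta * (1.0 - cosi * cosi);
      if (sint2 >= 1.0) { A.escaped += w; return; }
      double Rf = fresnel_R(cosi, n1, n2);
      w *= (1.0 - Rf); // deterministic specular subtraction
      double cost = std::sqrt(1.0 - sint2);
      double sgn = dir[entry] > 0 ? 1.0 : -1.0;
      for (int k = 0; k < 3; k++) dir[k] *= eta;
      dir[entry] = sgn * cost;
      double nn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
      for (int k = 0; k < 3; k++) dir[k] /= nn;
    }
  }

  double rs = -std::log(R.unif()); // dimensionless scattering path
  bool track = ndetector > 0 || mode == 1;
  double invd[3];
#define UPDATE_INVD() do { for (int q = 0; q < 3; q++) \
    invd[q] = dir[q] != 0.0 ? 1.0 / dir[q] : INF; } while (0)
  UPDATE_INVD();

  for (;;) {
    size_t idx = (size_t)iv[0] + (size_t)G.nx * (iv[1] + (size_t)G.ny * iv[2]);
    int lb;
    double mua_g, mus_g, gg, tpu, imus_g, itpu_g;
    if (G.fmt == 0) {
      lb = G.lab[idx];
      if (lb == 0) { // background voxel: photon leaves the medium here
        A.escaped += w;
        if (ndetector > 0) {
          for (int d = 0; d < ndetector; d++) {
            double dx = pos[0] - det[4*d], dy = pos[1] - det[4*d+1],
                   dz = pos[2] - det[4*d+2], r = det[4*d+3];
            if (dx*dx + dy*dy + dz*dz <= r*r) {
              std::vector<double> row;
              row.push_back(d + 1.0); row.push_back(w);
              for (int m = 0; m < M; m++) row.push_back(ppath[m]);
              for (int m = 0; m < M; m++) row.push_back((double)pscat[m]);
              for (int k = 0; k < 3; k++) row.push_back(pos[k]);
              for (int k = 0; k < 3; k++) row.push_back(dir[k]);
              row.push_back(mom); row.push_back(w0);
              row.push_back((double)(uint32_t)(pkey & 0xFFFFFFFFULL));
              row.push_back((double)(uint32_t)(pkey >> 32));
              A.ndetcol = row.size();
              A.detp.insert(A.detp.end(), row.begin(), row.end());
              A.ndet++;
              break;
            }
          }
        }
        if (out_pathsum) *out_pathsum = pathsum;
        return;
      }
      mua_g = G.mua[lb]; mus_g = G.mus[lb]; gg = G.g[lb]; tpu = G.tpu[lb];
      imus_g = G.imus[lb]; itpu_g = G.itpu[lb];
    } else {
      lb = 1;
      mua_g = G.fvol[2 * idx] * G.unit;
      mus_g = G.fvol[2 * idx + 1] * G.unit;
      gg = G.g[1]; tpu = G.tpu[1];
      imus_g = mus_g > 0 ? 1.0 / mus_g : INF;
      itpu_g = G.itpu[1];
    }

    // segment length candidates (grid units)
    double Lscat = mus_g > 0 ? rs * imus_g : INF;
    double Ltime = (t1 - t) * itpu_g;
    double db[3];
    int bax = 0;
    for (int k = 0; k < 3; k++) {
      if (dir[k] > 0)      db[k] = ((double)(iv[k] + 1) - pos[k]) * invd[k];
      else if (dir[k] < 0) db[k] = ((double)iv[k] - pos[k]) * invd[k];
      else                 db[k] = INF;
      if (db[k] < 0) db[k] = 0;
    }
    if (db[1] < db[bax]) bax = 1;
    if (db[2] < db[bax]) bax = 2;
    double Lbnd = db[bax];

    int ev; // 0 boundary, 1 scatter, 2 time expiry
    double L;
    if (Ltime <= Lscat && Ltime <= Lbnd) { ev = 2; L = Ltime; }
    else if (Lscat < Lbnd)               { ev = 1; L = Lscat; }
    else                                 { ev = 0; L = Lbnd; }

    // deposit along the segment; zero-mua voxels accumulate weighted
    // pathlength (mm) instead of absorbed energy (normalization fallback)
    double seg_mm = L * G.unit;
    int gate = 0;
    bool in_gate = t >= t0;
    if (ngate > 1) {
      gate = (int)((t - t0) / dt);
      if (gate < 0) { gate = 0; in_gate = false; }
      if (gate >= ngate) gate = ngate - 1;
    }
    if (mua_g > 0) {
      double dw = w * one_minus_exp_neg(mua_g * L);
      if (in_gate) { flu[idx + G.nvox * (size_t)gate] += dw; nev[idx]++; }
      A.absorbed += dw;
      w -= dw;
    } else if (L > 0 && in_gate) {
      flu[idx + G.nvox * (size_t)gate] += w * seg_mm;
      nev[idx]++;
    }
    if (track && lb >= 1 && lb <= M) ppath[lb - 1] += seg_mm;
    if (mode == 1) {
      jac[idx] += replay_w * seg_mm;
      pathsum += seg_mm;
    }
    t += L * tpu;
    for (int k = 0; k < 3; k++) pos[k] += dir[k] * L;
    rs -= L * mus_g;

    if (ev == 2) { // time gate closed
      A.expired += w;
      if (out_pathsum) *out_pathsum = pathsum;
      return;
    }
    if (ev == 1) { // scattering event
      double ct = hg_cos(gg, R.unif());
      scatter_dir(dir, ct, R);
      UPDATE_INVD();
      mom += 1.0 - ct;
      if (track && lb >= 1 && lb <= M) pscat[lb - 1]++;
      rs = -std::log(R.unif());
      if (w < rr_thresh * w0) { // Russian roulette
        if (R.unif() <= rr_p) {
          A.rrnet -= w * (1.0 / rr_p - 1.0);
          w /= rr_p;
        } else {
          A.rrnet += w;
          if (out_pathsum) *out_pathsum = pathsum;
          return;
        }
      }
      continue;
    }

    // boundary crossing: process every axis tied at the minimum distance
    bool terminated = false;
    for (int k = 0; k < 3 && !terminated; k++) {
      if (db[k] != Lbnd) continue;
      int sgn = dir[k] > 0 ? 1 : (dir[k] < 0 ? -1 : 0);
      if (sgn == 0) continue;
      int ni = iv[k] + sgn;
      if (ni < 0 || ni >= lims[k]) {
        // bounding-box face
        int face = 2 * k + (sgn > 0 ? 1 : 0);
        int code = bc[face];
        if (code == BC_MIRROR) {
          dir[k] = -dir[k]; invd[k] = -invd[k];
        } else if (code == BC_CYCLIC) {
          if (sgn > 0) { pos[k] -= lims[k]; iv[k] = 0; }
          else         { pos[k] += lims[k]; iv[k] = lims[k] - 1; }
          if (pos[k] < 0) pos[k] = 0;
          if (pos[k] >= lims[k]) pos[k] = lims[k] * (1.0 - 1e-15);
        } else if (code == BC_FRESNEL) {
          double n1 = G.n[lb], n2 = G.n[0];
          double cosi = std::fabs(dir[k]);
          double eta = n1 / n2;
          double sint2 = eta * eta * (1.0 - cosi * cosi);
          double Rf = sint2 >= 1.0 ? 1.0 : fresnel_R(cosi, n1, n2);
          if (R.unif() <= Rf) {
            dir[k] = -dir[k]; invd[k] = -invd[k];
          } else {
            // refract the exit direction, then escape
            double cost = std::sqrt(1.0 - sint2);
            for (int m = 0; m < 3; m++) dir[m] *= eta;
            dir[k] = (double)sgn * cost;
            double nn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
            for (int m = 0; m < 3; m++) dir[m] /= nn;
            code = BC_ABSORB; // fall through to escape handling below
          }
        }
        if (code == BC_ABSORB) {
          A.escaped += w;
          if (ndetector > 0) {
            for (int d = 0; d < ndetector; d++) {
              double dx = pos[0] - det[4*d], dy = pos[1] - det[4*d+1],
                     dz = pos[2] - det[4*d+2], r = det[4*d+3];
              if (dx*dx + dy*dy + dz*dz <= r*r) {
                std::vector<double> row;
                row.push_back(d + 1.0); row.push_back(w);
                for (int m = 0; m < M; m++) row.push_back(ppath[m]);
                for (int m = 0; m < M; m++) row.push_back((double)pscat[m]);
                for (int m = 0; m < 3; m++) row.push_back(pos[m]);
                for (int m = 0; m < 3; m++) row.push_back(dir[m]);
                row.push_back(mom); row.push_back(w0);
                row.push_back((double)(uint32_t)(pkey & 0xFFFFFFFFULL));
                row.push_back((double)(uint32_t)(pkey >> 32));
                A.ndetcol = row.size();
                A.detp.insert(A.detp.end(), row.begin(), row.end());
                A.ndet++;
                break;
              }
            }
          }
          if (out_pathsum) *out_pathsum = pathsum;
          terminated = true;
        }
      } else {
        // internal voxel face; refractive handling under mismatch
        if (mismatch && G.fmt == 0) {
          size_t nidx = idx + (size_t)sgn *
            (k == 0 ? 1 : (k == 1 ? (size_t)G.nx : (size_t)G.nx * G.ny));
          int nl = G.lab[nidx];
          double n1 = G.n[lb], n2 = G.n[nl];
          if (n1 != n2) {
            double cosi = std::fabs(dir[k]);
            double eta = n1 / n2;
            double sint2 = eta * eta * (1.0 - cosi * cosi);
            double Rf = sint2 >= 1.0 ? 1.0 : fresnel_R(cosi, n1, n2);
            if (R.unif() <= Rf) {
              dir[k] = -dir[k]; invd[k] = -invd[k]; // reflect, stay
              continue;
            }
            double cost = std::sqrt(1.0 - sint2);
            for (int m = 0; m < 3; m++) dir[m] *= eta;
            dir[k] = (double)sgn * cost;
            double nn = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
            for (int m = 0; m < 3; m++) dir[m] /= nn;
            UPDATE_INVD();
          }
        }
        iv[k] = ni;
      }
    }
    if (terminated) {
      if (out_pathsum) *out_pathsum = pathsum;
      return;
    }
    if (!R_FINITE(pos[0]) || !R_FINITE(pos[1]) || !R_FINITE(pos[2]))
      stop("internal consistency failure: non-finite photon position");
  }
}

static Grid parse_grid(SEXP vol_, int media_format, NumericMatrix media,
                       IntegerVector dim_, double unitinmm) {
  Grid G;
  G.fmt = media_format;
  G.nx = dim_[0]; G.ny = dim_[1]; G.nz = dim_[2];
  G.nvox = (size_t)G.nx * G.ny * G.nz;
  G.unit = unitinmm;
  G.lab = nullptr; G.fvol = nullptr;
  if (media_format == 0) {
    IntegerVector v(vol_);
    if ((size_t)v.size() != G.nvox) stop("volume size does not match Dim");
    G.lab = INTEGER(v);
  } else {
    NumericVector v(vol_);
    if ((size_t)v.size() != 2 * G.nvox)
      stop("float volume must hold (mua, mus) pairs per voxel");
    G.fvol = REAL(v);
  }
  int nm = media.nrow();
  G.mua.resize(nm); G.mus.resize(nm); G.g.resize(nm);
  G.n.resize(nm); G.tpu.resize(nm);
  G.imus.resize(nm); G.itpu.resize(nm);
  for (int i = 0; i < nm; i++) {
    G.mua[i] = media(i, 0) * unitinmm; // per grid unit
    G.mus[i] = media(i, 1) * unitinmm;
    G.g[i] = media(i, 2);
    G.n[i] = media(i, 3);
    G.tpu[i] = media(i, 3) * unitinmm / C0_MM_S;
    G.imus[i] = G.mus[i] > 0 ? 1.0 / G.mus[i] : INF;
    G.itpu[i] = 1.0 / G.tpu[i];
  }
  return G;
}

// [[Rcpp::export]]
List cpp_run_kernel(SEXP vol, int media_format, NumericMatrix media,
                    IntegerVector dim, double unitinmm,
                    double t0, double t1, double dt,
                    List src, NumericMatrix det, IntegerVector bc,
                    bool do_mismatch, double rr_thresh, double rr_p,
                    double nphotons, int seed, int worker,
                    int mode, NumericMatrix replay_keys,
                    NumericVector replay_weights) {
  Grid G = parse_grid(vol, media_format, media, dim, unitinmm);
  Source S = parse_source(src);
  int ngate = (int)std::lround((t1 - t0) / dt);
  if (ngate < 1) ngate = 1;

  NumericVector flu((R_xlen_t)(G.nvox * ngate));
  IntegerVector nev((R_xlen_t)G.nvox);
  NumericVector jac(mode == 1 ? (R_xlen_t)G.nvox : 0);
  std::fill(flu.begin(), flu.end(), 0.0);
  std::fill(nev.begin(), nev.end(), 0);
  if (mode == 1) std::fill(jac.begin(), jac.end(), 0.0);

  int bcv[6];
  for (int k = 0; k < 6; k++) bcv[k] = bc[k];
  int ndetector = det.nrow();
  std::vector<double> detv(4 * (size_t)std::max(ndetector, 1), 0.0);
  for (int d = 0; d < ndetector; d++)
    for (int k = 0; k < 4; k++) detv[4 * d + k] = det(d, k);

  RunAccum A;
  uint64_t wkey = worker_key(seed, worker);
  NumericVector pathsum;

  if (mode == 0) {
    uint64_t n = (uint64_t)nphotons;
    for (uint64_t i = 0; i < n; i++) {
      uint64_t pk = photon_key(wkey, i);
      transport(G, S, pk, t0, t1, dt, ngate, detv.data(), ndetector,
                bcv, do_mismatch, rr_thresh, rr_p,
                REAL(flu), INTEGER(nev), A, 0, 0.0, nullptr, nullptr);
      if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    int n = replay_keys.nrow();
    pathsum = NumericVector(n);
    for (int i = 0; i < n; i++) {
      uint64_t pk = (uint64_t)(uint32_t)replay_keys(i, 0) |
                    ((uint64_t)(uint32_t)replay_keys(i, 1) << 32);
      double ps = 0.0;
      transport(G, S, pk, t0, t1, dt, ngate, detv.data(), ndetector,
                bcv, do_mismatch, rr_thresh, rr_p,
                REAL(flu), INTEGER(nev), A, 1, replay_weights[i],
                REAL(jac), &ps);
      pathsum[i] = ps;
    }
  }

  NumericMatrix detp(0, 0);
  if (A.ndet > 0) {
    detp = NumericMatrix((int)A.ndet, (int)A.ndetcol);
    for (size_t i = 0; i < A.ndet; i++)
      for (size_t j = 0; j < A.ndetcol; j++)
        detp(i, j) = A.detp[i * A.ndetcol + j];
  }

  flu.attr("dim") = IntegerVector::create(G.nx, G.ny, G.nz, ngate);
  nev.attr("dim") = IntegerVector::create(G.nx, G.ny, G.nz);
  List out = List::create(
    _["flux"] = flu, _["nevents"] = nev, _["detp"] = detp,
    _["absorbed"] = A.absorbed, _["escaped"] = A.escaped,
    _["expired"] = A.expired, _["roulette_net"] = A.rrnet,
    _["launched"] = A.launched, _["nphoton"] = nphotons,
    _["gates"] = ngate);
  if (mode == 1) {
    jac.attr("dim") = IntegerVector::create(G.nx, G.ny, G.nz);
    out["jacobian"] = jac;
    out["pathsum"] = pathsum;
  }
  return out;
}

// ------------------------------------------------- standalone samplers ----

// [[Rcpp::export]]
NumericMatrix cpp_sample_launch(List src, double n, int seed, int worker) {
  Source S = parse_source(src);
  uint64_t wkey = worker_key(seed, worker);
  uint64_t nn = (uint64_t)n;
  NumericMatrix out((int)nn, 7);
  for (uint64_t i = 0; i < nn; i++) {
    Stream R;
    R.seed(photon_key(wkey, i));
    double pos[3], dir[3], w;
    launch(S, R, pos, dir, w);
    for (int k = 0; k < 3; k++) { out(i, k) = pos[k]; out(i, 3 + k) = dir[k]; }
    out(i, 6) = w;
  }
  colnames(out) = CharacterVector::create("x", "y", "z",
                                          "vx", "vy", "vz", "w");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_hg_sample(double n, double g, int seed) {
  Stream R;
  R.seed(mix64((uint64_t)(uint32_t)seed));
  uint64_t nn = (uint64_t)n;
  NumericVector out((R_xlen_t)nn);
  for (uint64_t i = 0; i < nn; i++) out[i] = hg_cos(g, R.unif());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_path_sample(double n, int seed) {
  Stream R;
  R.seed(mix64((uint64_t)(uint32_t)seed));
  uint64_t nn = (uint64_t)n;
  NumericVector out((R_xlen_t)nn);
  for (uint64_t i = 0; i < nn; i++) out[i] = -std::log(R.unif());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fresnel(NumericVector cosi, double n1, double n2) {
  NumericVector out(cosi.size());
  for (R_xlen_t i = 0; i < cosi.size(); i++)
    out[i] = fresnel_R(cosi[i], n1, n2);
  return out;
}
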