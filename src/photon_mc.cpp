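// Layered-slab photon transport for through-skull sensitivity estimation.
//
// Photons are launched at the center of the top face within the collection
// NA cone (reciprocity with a point detector), propagated absorption-free
// with per-layer exponential step sampling and Henyey-Greenstein
// scattering, refracted/reflected at layer and medium-air interfaces
// (Snell + unpolarized Fresnel, total internal reflection included), and
// collected when they exit the top face within the NA cone. Per-layer
// path lengths and path lengths within a designated layer's center row of
// voxel columns are accumulated for post-hoc Beer-law weighting.
//
// Absorption is deliberately absent from propagation: weights are applied
// afterwards from the stored path lengths, which is what makes the
// perturbation re-weighting exact.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]: safe as -log() argument
  inline double unif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// unpolarized Fresnel reflectance; cos_t receives the transmitted cosine
inline double fresnel_unpol(double n1, double n2, double cos_i,
                            double &cos_t) {
  double sin_i2 = 1.0 - cos_i * cos_i;
  if (sin_i2 < 0) sin_i2 = 0;
  const double r = n1 / n2;
  const double sin_t2 = r * r * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  cos_t = std::sqrt(1.0 - sin_t2);
  const double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  const double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein deflection cosine
inline double hg_cost(double g, double u) {
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  const double q = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - q * q) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

inline void scatter(double &ux, double &uy, double &uz, double g,
                    Xoshiro256pp &rng) {
  const double cost = hg_cost(g, rng.unif());
  const double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  // azimuth by rejection sampling of a point in the unit disc (avoids
  // the trigonometric calls in the innermost loop)
  double cosp, sinp;
  for (;;) {
    const double a = 2.0 * rng.unif() - 1.0;
    const double b = 2.0 * rng.unif() - 1.0;
    const double r2 = a * a + b * b;
    if (r2 > 1.0 || r2 < 1e-12) continue;
    cosp = (a * a - b * b) / r2;
    sinp = 2.0 * a * b / r2;
    break;
  }
  if (std::fabs(uz) > 0.999999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    const double den = std::sqrt(1.0 - uz * uz);
    const double nx = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    const double ny = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    const double nz = -sint * cosp * den + uz * cost;
    ux = nx; uy = ny; uz = nz;
  }
  // renormalize to stop drift over many scatters
  const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

}  // namespace

// walk one 2-D segment (start, direction, length) through the center-row
// voxel columns (|y| <= pitch/2, x binned at `pitch`), accumulating the
// in-voxel path lengths into the sparse (ix -> path) pair vectors
static inline void score_segment(double x, double y, double ux, double uy,
                                 double len, double pitch,
                                 std::vector<int> &ixs,
                                 std::vector<double> &pxs) {
  const double half_pitch = pitch / 2.0;
  double tlo = 0.0, thi = len;
  if (std::fabs(uy) < 1e-12) {
    if (std::fabs(y) > half_pitch) return;
  } else {
    const double t1 = (-half_pitch - y) / uy;
    const double t2 = (half_pitch - y) / uy;
    tlo = std::max(tlo, std::min(t1, t2));
    thi = std::min(thi, std::max(t1, t2));
  }
  if (thi <= tlo) return;
  double t = tlo;
  while (t < thi - 1e-12) {
    const double xc = x + ux * t;
    const int ix = static_cast<int>(std::floor(xc / pitch + 0.5));
    double tn;
    if (ux > 1e-12) tn = ((ix + 0.5) * pitch - x) / ux;
    else if (ux < -1e-12) tn = ((ix - 0.5) * pitch - x) / ux;
    else tn = thi;
    if (tn <= t + 1e-12) tn = t + 1e-12;
    const double tend = std::min(tn, thi);
    const double seg = tend - t;
    if (seg > 0) {
      bool found = false;
      for (size_t q = 0; q < ixs.size(); ++q)
        if (ixs[q] == ix) { pxs[q] += seg; found = true; break; }
      if (!found) { ixs.push_back(ix); pxs.push_back(seg); }
    }
    t = tend;
  }
}

// [[Rcpp::export(name = ".photon_mc")]]
List photon_mc(NumericVector thickness_mm, NumericVector mu_s,
               NumericVector g, NumericVector n_idx,
               double ambient_n, double lateral_halfwidth_mm,
               double na, double n_photons, double seed,
               double max_path_mm, int voxel_layer,
               double voxel_pitch_mm, int n_rotations) {
  const int K = thickness_mm.size();
  if (K < 1) stop("need at least one layer");
  if (na <= 0 || na >= 1) stop("NA must be in (0, 1)");
  if (n_photons < 1) stop("need at least one photon");
  if (voxel_layer < 1 || voxel_layer > K) stop("voxel_layer out of range");

  std::vector<double> zhi(K + 1, 0.0);
  for (int i = 0; i < K; ++i) zhi[i + 1] = zhi[i] + thickness_mm[i];
  std::vector<double> inv_mus(K);
  for (int i = 0; i < K; ++i) inv_mus[i] = 1.0 / mu_s[i];
  const double hw = lateral_halfwidth_mm;
  const int vlay = voxel_layer - 1;
  if (n_rotations < 1) stop("n_rotations must be >= 1");

  Xoshiro256pp rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1);

  const long long NP = static_cast<long long>(n_photons);
  long long n_collected = 0, n_escaped = 0, n_terminated = 0;

  std::vector<double> layer_paths;   // collected photons x K, row-major
  std::vector<double> exit_dirs;     // collected photons x 3
  std::vector<int> vox_photon, vox_rot, vox_ix;
  std::vector<double> vox_path;

  const double cos_max = std::sqrt(1.0 - na * na);

  std::vector<double> lp(K);
  // in-plane record of the photon's segments within the scored layer;
  // scored against the (rotated) center voxel row only on collection
  std::vector<double> seg_x, seg_y, seg_ux, seg_uy, seg_len;
  std::vector<int> ph_ix;
  std::vector<double> ph_px;

  for (long long p = 0; p < NP; ++p) {
    if ((p & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    // launch: uniform over the NA cone in air, at the top-face center
    const double cosa = cos_max + (1.0 - cos_max) * rng.unif();
    const double sina = std::sqrt(std::max(0.0, 1.0 - cosa * cosa));
    const double phi0 = 2.0 * M_PI * rng.unif();
    double ux = sina * std::cos(phi0), uy = sina * std::sin(phi0);
    double uz = cosa;  // +z is down into the medium
    // air -> first layer interface at launch
    double cos_t;
    const double R0 = fresnel_unpol(ambient_n, n_idx[0], cosa, cos_t);
    if (rng.unif() < R0) { ++n_escaped; continue; }
    {
      const double scale = ambient_n / n_idx[0];
      ux *= scale; uy *= scale;
      uz = cos_t;
      const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
      ux /= nrm; uy /= nrm; uz /= nrm;
    }

    double x = 0.0, y = 0.0, z = 0.0;
    int lay = 0;
    double total = 0.0;
    std::fill(lp.begin(), lp.end(), 0.0);
    seg_x.clear(); seg_y.clear(); seg_ux.clear(); seg_uy.clear();
    seg_len.clear();

    int fate = -1;  // 0 collected, 1 escaped, 2 terminated
    double ex_ux = 0, ex_uy = 0, ex_uz = 0;

    while (fate < 0) {
      const double step = -std::log(rng.unif_pos()) * inv_mus[lay];
      // distances to the bounding faces along the current direction
      double dz_b = 1e30; int zface = 0;  // -1 top of layer, +1 bottom
      if (uz > 1e-12) { dz_b = (zhi[lay + 1] - z) / uz; zface = 1; }
      else if (uz < -1e-12) { dz_b = (zhi[lay] - z) / uz; zface = -1; }
      double dx_b = 1e30;
      if (ux > 1e-12) dx_b = (hw - x) / ux;
      else if (ux < -1e-12) dx_b = (-hw - x) / ux;
      double dy_b = 1e30;
      if (uy > 1e-12) dy_b = (hw - y) / uy;
      else if (uy < -1e-12) dy_b = (-hw - y) / uy;
      if (dz_b < 0) dz_b = 0;
      if (dx_b < 0) dx_b = 0;
      if (dy_b < 0) dy_b = 0;

      double db = dz_b; int event = 0;          // 0 z-face, 1 x-face, 2 y-face
      if (dx_b < db) { db = dx_b; event = 1; }
      if (dy_b < db) { db = dy_b; event = 2; }
      const bool hits_boundary = db <= step;
      const double travel = hits_boundary ? db : step;

      // remember in-plane segments within the scored layer; they are
      // walked through the (rotated) voxel row only if collected
      if (lay == vlay && travel > 0) {
        seg_x.push_back(x); seg_y.push_back(y);
        seg_ux.push_back(ux); seg_uy.push_back(uy);
        seg_len.push_back(travel);
      }

      x += ux * travel; y += uy * travel; z += uz * travel;
      lp[lay] += travel;
      total += travel;
      if (total >= max_path_mm) { fate = 2; break; }

      if (!hits_boundary) {
        scatter(ux, uy, uz, g[lay], rng);
        continue;
      }

      if (event == 1 || event == 2) {
        // lateral face: medium -> air
        double &un = (event == 1) ? ux : uy;
        const double cos_i = std::fabs(un);
        double ct;
        const double R = fresnel_unpol(n_idx[lay], ambient_n, cos_i, ct);
        if (rng.unif() < R) { un = -un; continue; }
        fate = 1;  // escaped sideways
        continue;
      }

      // z-face
      if (zface < 0 && lay == 0) {
        // top face: skull -> air, the collection side
        const double cos_i = -uz;  // uz < 0 going up
        double ct;
        const double R = fresnel_unpol(n_idx[0], ambient_n, cos_i, ct);
        if (rng.unif() < R) { uz = -uz; continue; }
        const double scale = n_idx[0] / ambient_n;
        double tx = ux * scale, ty = uy * scale;
        const double sin_out2 = tx * tx + ty * ty;
        ex_ux = tx; ex_uy = ty; ex_uz = -ct;
        fate = (sin_out2 <= na * na) ? 0 : 1;
        continue;
      }
      if (zface > 0 && lay == K - 1) {
        // bottom face: medium -> air
        const double cos_i = uz;
        double ct;
        const double R = fresnel_unpol(n_idx[lay], ambient_n, cos_i, ct);
        if (rng.unif() < R) { uz = -uz; continue; }
        fate = 1;
        continue;
      }
      // internal interface between lay and lay +- 1
      {
        const int nxt = lay + (zface > 0 ? 1 : -1);
        const double n1 = n_idx[lay], n2 = n_idx[nxt];
        const double cos_i = std::fabs(uz);
        double ct;
        const double R = fresnel_unpol(n1, n2, cos_i, ct);
        if (rng.unif() < R) { uz = -uz; continue; }
        const double scale = n1 / n2;
        ux *= scale; uy *= scale;
        uz = (uz > 0 ? ct : -ct);
        const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
        lay = nxt;
        continue;
      }
    }

    if (fate == 0) {
      ++n_collected;
      for (int i = 0; i < K; ++i) layer_paths.push_back(lp[i]);
      exit_dirs.push_back(ex_ux);
      exit_dirs.push_back(ex_uy);
      exit_dirs.push_back(ex_uz);
      // azimuthal averaging: score the trajectory against n_rotations
      // stratified rotations of the center voxel row about the optical
      // axis (launch and collection are axially symmetric, so every
      // rotation of a collected trajectory is equally probable)
      const double u0 = rng.unif();
      for (int m = 0; m < n_rotations; ++m) {
        double c = 1.0, sn = 0.0;
        if (n_rotations > 1) {
          const double th = 2.0 * M_PI * (m + u0) / n_rotations;
          c = std::cos(th); sn = std::sin(th);
        }
        ph_ix.clear(); ph_px.clear();
        for (size_t q = 0; q < seg_x.size(); ++q) {
          const double rx = c * seg_x[q] + sn * seg_y[q];
          const double ry = -sn * seg_x[q] + c * seg_y[q];
          const double rux = c * seg_ux[q] + sn * seg_uy[q];
          const double ruy = -sn * seg_ux[q] + c * seg_uy[q];
          score_segment(rx, ry, rux, ruy, seg_len[q], voxel_pitch_mm,
                        ph_ix, ph_px);
        }
        for (size_t q = 0; q < ph_ix.size(); ++q) {
          vox_photon.push_back(static_cast<int>(n_collected));  // 1-based
          vox_rot.push_back(m + 1);
          vox_ix.push_back(ph_ix[q]);
          vox_path.push_back(ph_px[q]);
        }
      }
    } else if (fate == 1) {
      ++n_escaped;
    } else {
      ++n_terminated;
    }
  }

  const int NC = static_cast<int>(n_collected);
  NumericMatrix LP(NC, K), ED(NC, 3);
  for (int i = 0; i < NC; ++i) {
    for (int j = 0; j < K; ++j)
      LP(i, j) = layer_paths[static_cast<size_t>(i) * K + j];
    for (int j = 0; j < 3; ++j)
      ED(i, j) = exit_dirs[static_cast<size_t>(i) * 3 + j];
  }

  return List::create(
    _["layer_paths"] = LP,
    _["exit_dirs"] = ED,
    _["voxel_photon"] = IntegerVector(vox_photon.begin(), vox_photon.end()),
    _["voxel_rot"] = IntegerVector(vox_rot.begin(), vox_rot.end()),
    _["voxel_ix"] = IntegerVector(vox_ix.begin(), vox_ix.end()),
    _["voxel_path"] = NumericVector(vox_path.begin(), vox_path.end()),
    _["n_collected"] = static_cast<double>(n_collected),
    _["n_escaped"] = static_cast<double>(n_escaped),
    _["n_terminated"] = static_cast<double>(n_terminated));
}
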