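// Weighted Monte Carlo photon transport through a stack of plane-parallel
// slabs with an optional embedded cylinder (bone) whose axis is
// perpendicular to the optical (z) axis. Internal interfaces are
// index-matched; Fresnel reflection applies only at the two outer
// air-tissue surfaces, with deterministic weight splitting on exit. The
// medium may be laterally bounded (a finger has side faces): packets whose
// interaction site lies beyond the lateral half-width escape sideways.
//
// Variance reduction: optional importance planes perpendicular to z. A
// packet crossing a plane towards the detector splits in two (each child
// carrying half the weight); crossing away it plays roulette at survival
// 1/2 (doubling the survivor's weight). The roulette weight threshold is
// scaled by the local importance so the two mechanisms do not fight each
// other (a weight-window scheme). All tallies remain unbiased and exactly
// weight-conserving.
//
// RNG: xoshiro256++ seeded through splitmix64 from (seed, stream). Each
// launch batch owns one substream, so tallies are bit-reproducible and
// independent of scheduling. Exponential deviates use the Marsaglia-Tsang
// ziggurat.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cfloat>
#include <vector>

using namespace Rcpp;

namespace {

const double EPS_NUDGE = 1e-7;   // mm, post-crossing push into the new region
const double GEOM_EPS  = 1e-12;
const long   MAX_STEPS = 1000000L;
const int    MAX_PENDING = 8192; // split-packet stack; beyond it we stop splitting

// ---------------------------------------------------------------------------
// ziggurat tables for Exp(1) (Marsaglia & Tsang)

struct ZigExp {
  uint32_t ke[256];
  double we[256], fe[256];
  ZigExp() {
    const double m2 = 4294967296.0;
    double de = 7.697117470131487, te = de;
    const double ve = 3.949659822581572e-3;
    double q = ve / std::exp(-de);
    ke[0] = (uint32_t)((de / q) * m2);
    ke[1] = 0;
    we[0] = q / m2;
    we[255] = de / m2;
    fe[0] = 1.0;
    fe[255] = std::exp(-de);
    for (int i = 254; i >= 1; i--) {
      de = -std::log(ve / de + std::exp(-de));
      ke[i + 1] = (uint32_t)((de / te) * m2);
      te = de;
      fe[i] = std::exp(-de);
      we[i] = de / m2;
    }
  }
};

const ZigExp ZIG;

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t seed_, uint64_t stream) {
    uint64_t x = seed_ ^ (stream * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  uint32_t next32() { return (uint32_t)(next() >> 32); }

  // uniform on (0, 1]
  double unif_oc() { return ((next() >> 11) + 1) * 0x1.0p-53; }
  // uniform on [0, 1)
  double unif_co() { return (next() >> 11) * 0x1.0p-53; }

  // Exp(1) via ziggurat
  double rexp() {
    for (;;) {
      uint32_t jz = next32();
      uint32_t iz = jz & 255;
      if (jz < ZIG.ke[iz]) return jz * ZIG.we[iz];
      if (iz == 0) return 7.697117470131487 - std::log(unif_oc());
      double x = jz * ZIG.we[iz];
      if (ZIG.fe[iz] + unif_co() * (ZIG.fe[iz - 1] - ZIG.fe[iz]) <
          std::exp(-x)) return x;
    }
  }

  // standard normal pair via Box-Muller
  void normal2(double &a, double &b) {
    double r = std::sqrt(2.0 * rexp());
    double t = 2.0 * M_PI * unif_co();
    a = r * std::cos(t);
    b = r * std::sin(t);
  }

  // random point on the unit circle without trig (Marsaglia)
  void unit_circle(double &c, double &sn) {
    double a, b, rr;
    do {
      a = 2.0 * unif_co() - 1.0;
      b = 2.0 * unif_co() - 1.0;
      rr = a * a + b * b;
    } while (rr > 1.0 || rr == 0.0);
    double inv = 1.0 / rr;
    c = (a * a - b * b) * inv;
    sn = 2.0 * a * b * inv;
  }
};

double fresnel_unpolarized(double n1, double n2, double cos_i) {
  cos_i = std::fabs(cos_i);
  if (cos_i > 1.0) cos_i = 1.0;
  if (n1 == n2) return 0.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-9) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

void spin(double &ux, double &uy, double &uz, double cos_t,
          double cos_p, double sin_p) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - cos_t * cos_t));
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = sin_t * cos_p;
    ny = sin_t * sin_p;
    nz = cos_t * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    nx = sin_t * (ux * uz * cos_p - uy * sin_p) / tmp + ux * cos_t;
    ny = sin_t * (uy * uz * cos_p + ux * sin_p) / tmp + uy * cos_t;
    nz = -sin_t * cos_p * tmp + uz * cos_t;
  }
  double inv = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx * inv; uy = ny * inv; uz = nz * inv;
}

struct Geometry {
  int n_layers;
  const double *zb;                // interface depths, length n_layers + 1
  const double *mu_a, *mu_s, *g;   // per layer, trailing bone entry at [n_layers]
  bool has_bone;
  int bone_layer;
  double bone_z0, bone_r2;         // axis (y = 0, z = bone_z0), radius squared
  double lateral_r2;               // squared lateral half-width (side faces)
  const double *imp_z;             // importance planes (ascending), may be 0
  int n_imp;

  // region index: 0..n_layers-1 slabs, n_layers = bone interior
  int region_at(double y, double z) const {
    int lo = 0, hi = n_layers - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (z < zb[mid + 1]) hi = mid; else lo = mid + 1;
    }
    if (has_bone && lo == bone_layer) {
      double dz = z - bone_z0;
      if (y * y + dz * dz < bone_r2) return n_layers;
    }
    return lo;
  }

  int level_at(double z) const {
    int lv = 0;
    while (lv < n_imp && imp_z[lv] < z) ++lv;
    return lv;
  }

  double cylinder_dist(double y, double z, double uy, double uz,
                       bool inside) const {
    double a = uy * uy + uz * uz;
    if (a < GEOM_EPS) return DBL_MAX;  // parallel to the axis
    double fy = y, fz = z - bone_z0;
    double b = 2.0 * (fy * uy + fz * uz);
    double c = fy * fy + fz * fz - bone_r2;
    double disc = b * b - 4.0 * a * c;
    if (disc <= 0.0) return DBL_MAX;
    double sq = std::sqrt(disc);
    if (inside) {
      double t = (-b + sq) / (2.0 * a);
      return t > GEOM_EPS ? t : DBL_MAX;
    }
    double t0 = (-b - sq) / (2.0 * a);
    if (t0 > GEOM_EPS) return t0;
    return DBL_MAX;
  }
};

struct Tally {
  long double specular = 0.0L, absorbed = 0.0L, detected = 0.0L,
              escaped = 0.0L, residual = 0.0L;
  long long launched = 0, detected_count = 0, batches = 0;
  long long total_steps = 0;
};

struct Pending {
  double x, y, z, ux, uy, uz, w;
  int level;
};

struct Transporter {
  const Geometry &geo;
  Xoshiro &rng;
  Tally &tl;
  double n_tissue, n_ambient, src_sigma, det_r2, det_cos_min, w0, surv;
  std::vector<double> thr_lv;      // roulette threshold per importance level
  std::vector<Pending> pending;

  Transporter(const Geometry &geo_, Xoshiro &rng_, Tally &tl_,
              double n_tissue_, double n_ambient_, double src_sigma_,
              double det_r2_, double det_cos_min_, double w0_,
              double thr, double surv_)
    : geo(geo_), rng(rng_), tl(tl_), n_tissue(n_tissue_),
      n_ambient(n_ambient_), src_sigma(src_sigma_), det_r2(det_r2_),
      det_cos_min(det_cos_min_), w0(w0_), surv(surv_) {
    thr_lv.resize(geo.n_imp + 1);
    for (int k = 0; k <= geo.n_imp; ++k) thr_lv[k] = thr * std::ldexp(1.0, -k);
    pending.reserve(256);
  }

  // returns true when the packet survives roulette
  bool roulette(double &w, double thr) {
    if (w >= thr) return true;
    if (rng.unif_co() < surv) {
      tl.residual += w - w / surv;
      w /= surv;
      return true;
    }
    tl.residual += w;
    return false;
  }

  void track(double x, double y, double z, double ux, double uy, double uz,
             double w, int level);

  void one_photon() {
    double x, y;
    rng.normal2(x, y);
    track(x * src_sigma, y * src_sigma, 0.0, 0.0, 0.0, 1.0, w0, 0);
    while (!pending.empty()) {
      Pending p = pending.back();
      pending.pop_back();
      track(p.x, p.y, p.z, p.ux, p.uy, p.uz, p.w, p.level);
    }
  }
};

void Transporter::track(double x, double y, double z,
                        double ux, double uy, double uz,
                        double w, int level) {
  const double z_max = geo.zb[geo.n_layers];
  const bool matched = (n_tissue == n_ambient);

  int region = geo.region_at(y, z < z_max ? z : z_max - EPS_NUDGE);
  double mua = geo.mu_a[region], mus = geo.mu_s[region];
  double mu_t = mua + mus;
  double albedo = mu_t > 0 ? mus / mu_t : 0.0;

  double tau = rng.rexp();
  long steps = 0;

  enum { EV_INTERACT, EV_INTERNAL, EV_OUTER_MIN, EV_OUTER_MAX,
         EV_IMP_UP, EV_IMP_DOWN };

  while (true) {
    if (++steps > MAX_STEPS) { tl.residual += w; break; }

    // distance to the nearest boundary of the current region
    double db; int ev;
    if (region == geo.n_layers) {          // inside bone
      db = geo.cylinder_dist(y, z, uy, uz, true);
      ev = EV_INTERNAL;
    } else {
      if (uz > GEOM_EPS) {
        db = (geo.zb[region + 1] - z) / uz;
        ev = (region == geo.n_layers - 1) ? EV_OUTER_MAX : EV_INTERNAL;
      } else if (uz < -GEOM_EPS) {
        db = (geo.zb[region] - z) / uz;
        ev = (region == 0) ? EV_OUTER_MIN : EV_INTERNAL;
      } else {
        db = DBL_MAX; ev = EV_INTERNAL;
      }
      if (geo.has_bone && region == geo.bone_layer) {
        double dc = geo.cylinder_dist(y, z, uy, uz, false);
        if (dc < db) { db = dc; ev = EV_INTERNAL; }
      }
    }
    // importance planes compete with material boundaries
    if (geo.n_imp) {
      if (uz > GEOM_EPS && level < geo.n_imp) {
        double d = (geo.imp_z[level] - z) / uz;
        if (d >= 0 && d < db) { db = d; ev = EV_IMP_UP; }
      } else if (uz < -GEOM_EPS && level > 0) {
        double d = (geo.imp_z[level - 1] - z) / uz;
        if (d >= 0 && d < db) { db = d; ev = EV_IMP_DOWN; }
      }
    }
    if (db < 0) db = 0;

    double s = (mu_t > 0) ? tau / mu_t : DBL_MAX;

    if (s < db) {
      // hop to the interaction site
      x += s * ux; y += s * uy; z += s * uz;

      // side faces: interaction beyond the lateral extent escapes
      if (x * x + y * y > geo.lateral_r2) { tl.escaped += w; break; }

      // drop
      double dw = w * (1.0 - albedo);
      tl.absorbed += dw;
      w -= dw;
      if (w <= 0.0) break;  // pure absorber: nothing left to track
      if (!roulette(w, thr_lv[level])) break;

      // spin
      double cos_t = hg_cos(geo.g[region], rng.unif_co());
      double cos_p, sin_p;
      rng.unit_circle(cos_p, sin_p);
      spin(ux, uy, uz, cos_t, cos_p, sin_p);
      tau = rng.rexp();
      continue;
    }

    // advance to the boundary
    x += db * ux; y += db * uy; z += db * uz;
    if (mu_t > 0) {
      tau -= db * mu_t;
      if (tau < 0) tau = 0;
    }

    switch (ev) {
    case EV_OUTER_MIN:
    case EV_OUTER_MAX: {
      bool distal = (ev == EV_OUTER_MAX);
      double r_f = matched ? 0.0
        : fresnel_unpolarized(n_tissue, n_ambient, uz);
      double wt = w * (1.0 - r_f);
      if (wt > 0) {
        if (distal && (x * x + y * y) <= det_r2 && uz >= det_cos_min) {
          tl.detected += wt;
          tl.detected_count += 1;
        } else {
          tl.escaped += wt;
        }
      }
      w *= r_f;
      if (w <= 0.0) { steps = -steps; }  // mark termination
      else {
        uz = -uz;
        z = distal ? z_max - EPS_NUDGE : EPS_NUDGE;
        if (!roulette(w, thr_lv[level])) steps = -steps;
      }
      if (steps < 0) { steps = -steps; goto done; }
      break;
    }
    case EV_IMP_UP:
      // split in two; the child is parked and picked up later
      z += EPS_NUDGE * (uz > 0 ? 1.0 : -1.0);
      ++level;
      w *= 0.5;
      if ((int)pending.size() < MAX_PENDING) {
        pending.push_back(Pending{x, y, z, ux, uy, uz, w, level});
      } else {
        w *= 2.0;  // stack full: skip the split (still unbiased)
      }
      region = geo.region_at(y, z);
      mua = geo.mu_a[region]; mus = geo.mu_s[region];
      mu_t = mua + mus;
      albedo = mu_t > 0 ? mus / mu_t : 0.0;
      break;
    case EV_IMP_DOWN: {
      z += EPS_NUDGE * (uz > 0 ? 1.0 : -1.0);
      --level;
      // importance roulette at survival 1/2
      if (rng.unif_co() < 0.5) {
        tl.residual += w - 2.0 * w;
        w *= 2.0;
      } else {
        tl.residual += w;
        goto done;
      }
      region = geo.region_at(y, z);
      mua = geo.mu_a[region]; mus = geo.mu_s[region];
      mu_t = mua + mus;
      albedo = mu_t > 0 ? mus / mu_t : 0.0;
      break;
    }
    default:
      // index-matched internal interface: push into the new region,
      // carrying the remaining optical depth across
      x += EPS_NUDGE * ux; y += EPS_NUDGE * uy; z += EPS_NUDGE * uz;
      if (z <= 0.0) z = EPS_NUDGE;
      if (z >= z_max) z = z_max - EPS_NUDGE;
      region = geo.region_at(y, z);
      mua = geo.mu_a[region]; mus = geo.mu_s[region];
      mu_t = mua + mus;
      albedo = mu_t > 0 ? mus / mu_t : 0.0;
      break;
    }
  }
done:
  tl.total_steps += steps;
}

} // namespace

// [[Rcpp::export]]
double cpp_specular_reflectance(double n1, double n2) {
  double r = (n1 - n2) / (n1 + n2);
  return r * r;
}

// [[Rcpp::export]]
double cpp_fresnel_unpolarized(double n1, double n2, double cos_i) {
  return fresnel_unpolarized(n1, n2, cos_i);
}

// [[Rcpp::export]]
NumericVector cpp_sample_hg(double g, int n, double seed, double stream = 0) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos(g, rng.unif_co());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_free_path(double mu_t, int n, double seed,
                                   double stream = 0) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rexp() / mu_t;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_update_direction(NumericVector dir, double cos_t,
                                   double phi) {
  double ux = dir[0], uy = dir[1], uz = dir[2];
  spin(ux, uy, uz, cos_t, std::cos(phi), std::sin(phi));
  return NumericVector::create(ux, uy, uz);
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_gaussian_source(double sigma, int n, double seed,
                                         double stream = 0) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double a, b;
    rng.normal2(a, b);
    out(i, 0) = sigma * a;
    out(i, 1) = sigma * b;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_roulette(double w, double threshold, double survival,
                           int n, double seed, double stream = 0) {
  Xoshiro rng;
  rng.seed((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (w >= threshold) { out[i] = w; continue; }
    out[i] = (rng.unif_co() < survival) ? w / survival : 0.0;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_cylinder_distance(double y, double z, double uy, double uz,
                             double z0, double radius, bool inside) {
  Geometry geo;
  geo.bone_z0 = z0;
  geo.bone_r2 = radius * radius;
  double d = geo.cylinder_dist(y, z, uy, uz, inside);
  return d == DBL_MAX ? R_PosInf : d;
}

// [[Rcpp::export]]
List cpp_run_mc(NumericVector z_bounds,
                NumericVector mu_a, NumericVector mu_s, NumericVector g,
                bool has_bone, int bone_layer, double bone_z0, double bone_r,
                double bone_mu_a, double bone_mu_s, double bone_g,
                double n_tissue, double n_ambient,
                double src_sigma, double det_radius, double det_cos_min,
                double lateral_halfwidth,
                NumericVector importance_planes,
                double target_detected, double max_launched,
                double batch_size,
                double roulette_threshold, double roulette_survival,
                double seed, double stream_base) {
  int L = mu_a.size();
  std::vector<double> va(L + 1), vs(L + 1), vg(L + 1);
  for (int i = 0; i < L; ++i) { va[i] = mu_a[i]; vs[i] = mu_s[i]; vg[i] = g[i]; }
  va[L] = bone_mu_a; vs[L] = bone_mu_s; vg[L] = bone_g;

  Geometry geo;
  geo.n_layers = L;
  geo.zb = REAL(z_bounds);
  geo.mu_a = va.data(); geo.mu_s = vs.data(); geo.g = vg.data();
  geo.has_bone = has_bone;
  geo.bone_layer = bone_layer;
  geo.bone_z0 = bone_z0;
  geo.bone_r2 = bone_r * bone_r;
  geo.lateral_r2 = std::isfinite(lateral_halfwidth)
    ? lateral_halfwidth * lateral_halfwidth : DBL_MAX;
  geo.imp_z = importance_planes.size() ? REAL(importance_planes) : nullptr;
  geo.n_imp = importance_planes.size();

  double r_spec = (n_ambient == n_tissue)
    ? 0.0 : cpp_specular_reflectance(n_ambient, n_tissue);
  double det_r2 = det_radius * det_radius;

  Tally tl;
  long long target = (long long)target_detected;
  long long maxl = (long long)max_launched;
  long long bsize = (long long)batch_size;
  bool exhausted = false;

  for (long long batch = 0;; ++batch) {
    Xoshiro rng;
    rng.seed((uint64_t)seed, (uint64_t)(stream_base + (double)batch));
    Transporter tr(geo, rng, tl, n_tissue, n_ambient, src_sigma, det_r2,
                   det_cos_min, 1.0 - r_spec,
                   roulette_threshold, roulette_survival);
    tl.batches += 1;
    for (long long i = 0; i < bsize && tl.launched < maxl; ++i) {
      tl.launched += 1;
      tr.one_photon();
    }
    if (tl.detected_count >= target) break;
    if (tl.launched >= maxl) { exhausted = tl.detected_count < target; break; }
    Rcpp::checkUserInterrupt();
  }
  tl.specular = (long double)r_spec * (long double)tl.launched;

  return List::create(
    _["launched"] = (double)tl.launched,
    _["specular_weight"] = (double)tl.specular,
    _["absorbed_weight"] = (double)tl.absorbed,
    _["detected_weight"] = (double)tl.detected,
    _["detected_count"] = (double)tl.detected_count,
    _["escaped_weight"] = (double)tl.escaped,
    _["residual_weight"] = (double)tl.residual,
    _["batches"] = (double)tl.batches,
    _["total_steps"] = (double)tl.total_steps,
    _["budget_exhausted"] = exhausted);
}
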