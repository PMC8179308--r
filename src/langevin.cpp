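// BAOAB Langevin integrator on the constrained piecewise-quartic double well.
// Units here: length nm, time ps, mass amu, energy amu nm^2 ps^-2
// (1 kcal/mol = 4.184 amu nm^2 ps^-2; conversion done on the R side).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// xoshiro256+ with splitmix64 seeding; polar Box-Muller normals.
// Much faster than std::normal_distribution<std::mt19937_64> and fully
// reproducible across platforms for a given seed.
struct FastNormal {
  uint64_t s[4];
  double spare;
  bool has_spare;

  explicit FastNormal(uint64_t seed) : has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline double unif() {  // (0, 1)
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return ((result >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

struct DoubleWell {
  double zl, zr;      // well minima (zl < 0 < zr)
  double ea_f, ea_r;  // barrier heights (energy units), U(0) = 0
  double kl, kr;      // harmonic continuation stiffness beyond the minima

  DoubleWell(double zl_, double zr_, double eaf_, double ear_)
    : zl(zl_), zr(zr_), ea_f(eaf_), ea_r(ear_) {
    kl = 4.0 * ea_f / (zl * zl);
    kr = 4.0 * ea_r / (zr * zr);
  }
  // force = -dU/dz
  inline double force(double z) const {
    if (z < zl) return -kl * (z - zl);
    if (z <= 0.0) {
      double w = -zl, s = (z - zl) / w;
      return -ea_f * (4.0 * s - 4.0 * s * s * s) / w;
    }
    if (z <= zr) {
      double w = -zr, s = (z - zr) / w;  // s: 1 at 0 -> 0 at zr
      return -ea_f_right(s);
    }
    return -kr * (z - zr);
  }
  inline double ea_f_right(double s) const {
    return ea_r * (4.0 * s - 4.0 * s * s * s) / (-zr);
  }
  inline double energy(double z) const {
    if (z < zl) return -ea_f + 0.5 * kl * (z - zl) * (z - zl);
    if (z <= 0.0) {
      double s = (z - zl) / (-zl);
      return ea_f * (-1.0 + 2.0 * s * s - s * s * s * s);
    }
    if (z <= zr) {
      double s = (z - zr) / (-zr);
      return ea_r * (-1.0 + 2.0 * s * s - s * s * s * s);
    }
    return -ea_r + 0.5 * kr * (z - zr) * (z - zr);
  }
};

// [[Rcpp::export(name = ".ld_potential_cpp")]]
Rcpp::List ld_potential_cpp(Rcpp::NumericVector z, double zl, double zr,
                            double ea_f, double ea_r) {
  DoubleWell dw(zl, zr, ea_f, ea_r);
  int n = z.size();
  Rcpp::NumericVector U(n), F(n);
  for (int i = 0; i < n; ++i) { U[i] = dw.energy(z[i]); F[i] = dw.force(z[i]); }
  return Rcpp::List::create(Rcpp::Named("U") = U, Rcpp::Named("F") = F);
}

// [[Rcpp::export(name = ".ld_simulate_cpp")]]
Rcpp::List ld_simulate_cpp(double zl, double zr, double ea_f, double ea_r,
                           double mass, double kT, double gamma, double dt,
                           int n_inner, int n_samples, int n_reps,
                           double seed, int vel_stride, int store_reps,
                           int hist_bins, double hist_lo, double hist_hi) {
  DoubleWell dw(zl, zr, ea_f, ea_r);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  const double vsig = std::sqrt(kT / mass);
  const double half_dt_over_m = 0.5 * dt / mass;
  const double zmax = 10.0 * std::max(std::fabs(zl), std::fabs(zr));
  const double hbw = (hist_hi - hist_lo) / hist_bins;

  Rcpp::IntegerVector fwd(n_reps), bwd(n_reps);
  Rcpp::NumericVector left_frac(n_reps);
  Rcpp::NumericVector zhist(hist_bins);
  std::vector<double> vels;
  Rcpp::NumericMatrix traj(store_reps > 0 ? n_samples : 0, store_reps);

  const uint64_t base = (uint64_t)seed;
  long vcount = 0;

  for (int rep = 0; rep < n_reps; ++rep) {
    FastNormal gauss(base + 0x9E3779B97F4A7C15ULL * (uint64_t)(rep + 1));
    double z = zl;
    double v = vsig * gauss.norm();
    double F = dw.force(z);
    int state = 0;  // 0 = left basin, 1 = right
    long nleft = 0;
    for (int s = 0; s < n_samples; ++s) {
      for (int k = 0; k < n_inner; ++k) {
        v += half_dt_over_m * F;
        z += 0.5 * dt * v;
        v = c1 * v + c2 * gauss.norm();
        z += 0.5 * dt * v;
        F = dw.force(z);
        v += half_dt_over_m * F;
        // hysteresis crossing counter: switch only on reaching the other
        // minimum (checked in continuous time, every inner step)
        if (state == 0) {
          if (z >= zr) { state = 1; fwd[rep]++; }
        } else {
          if (z <= zl) { state = 0; bwd[rep]++; }
        }
      }
      if (std::fabs(z) > zmax)
        Rcpp::stop("divergent Langevin trajectory (|z| > %.2f); use a smaller dt", zmax);
      if (z < 0.0) nleft++;
      int hb = (int)((z - hist_lo) / hbw);
      if (hb >= 0 && hb < hist_bins) zhist[hb] += 1.0;
      if (vel_stride > 0 && (vcount++ % vel_stride) == 0) vels.push_back(v);
      if (rep < store_reps) traj(s, rep) = z;
    }
    left_frac[rep] = (double)nleft / n_samples;
    if ((rep & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("forward") = fwd, Rcpp::Named("backward") = bwd,
    Rcpp::Named("left_fraction") = left_frac,
    Rcpp::Named("z_hist") = zhist,
    Rcpp::Named("velocities") = Rcpp::wrap(vels),
    Rcpp::Named("traj") = traj);
}
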