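// White (zero-absorption) Monte Carlo photon random walk in a layered slab.
//
// Photons are launched as a pencil beam normal to the top surface. Free
// paths are sampled in optical-depth units and converted to geometric
// distance with the local scattering coefficient, so the leftover depth is
// carried correctly across interfaces between layers of different mus
// (the MCML convention). Per-layer path lengths are accumulated by
// splitting every step at layer boundaries, and photons escaping the top
// surface through the Fresnel interface are tallied either on annular
// rings centered on their source (default; exploits the lateral
// homogeneity of the medium) or on discrete disc detectors.
// No absorption is applied here: absorption (and the modulation phase)
// enter later by exact re-weighting of the recorded per-layer paths.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- xoshiro256+ with splitmix64 seeding: fast, high-quality stream per
//      (seed, source) so runs are reproducible and sources independent.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // uniform on (0, 1]
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
};

static inline double fresnel_unpol(double cos_i, double n_i, double n_t) {
  cos_i = std::fabs(cos_i);
  if (cos_i > 1.0) cos_i = 1.0;
  double sin2_i = 1.0 - cos_i * cos_i;
  double sin2_t = (n_i / n_t) * (n_i / n_t) * sin2_i;
  if (sin2_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin2_t);
  double rs = (n_i * cos_i - n_t * cos_t) / (n_i * cos_i + n_t * cos_t);
  double rp = (n_i * cos_t - n_t * cos_i) / (n_i * cos_t + n_t * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
double fresnel_R_cpp(double cos_theta, double n_in, double n_out) {
  return fresnel_unpol(cos_theta, n_in, n_out);
}

// unit vector in the plane, by rejection (no trig)
static inline void rand_azimuth(Xoshiro &rng, double &c, double &sn) {
  double a, b, r2;
  do {
    a = 2.0 * rng.u01() - 1.0;
    b = 2.0 * rng.u01() - 1.0;
    r2 = a * a + b * b;
  } while (r2 > 1.0 || r2 < 1e-12);
  double inv = 1.0 / std::sqrt(r2);
  c = a * inv; sn = b * inv;
}

// boundaries: z of the BOTTOM of each layer (length = n layers, increasing,
// last = box depth); the top surface is z = 0.
// rings: nring x 2 (inner, outer) radii, used when annular = true.
// det_xy: ndet x 2 disc-detector centers, used when annular = false.
// Fates: 0 detected, 1 top-escape outside detectors, 2 lateral escape,
//        3 bottom escape, 4 path-cutoff termination.
// [[Rcpp::export]]
List mc_kernel(NumericVector boundaries, NumericVector mus, NumericVector g,
               NumericVector n_layer, double n_out,
               NumericVector xlim, NumericVector ylim,
               NumericVector src_x, NumericVector src_y,
               NumericMatrix det_xy, double det_radius,
               NumericMatrix rings, bool annular,
               double n_photons_per_source, int seed, double max_path) {
  const int nl = boundaries.size();
  const int nsrc = src_x.size();
  const int ndet_t = annular ? rings.nrow() : det_xy.nrow();
  const long long npp = (long long)n_photons_per_source;

  std::vector<double> zbot(boundaries.begin(), boundaries.end());
  std::vector<double> lp(nl);
  const bool uniform_n = [&] {
    for (int j = 1; j < nl; ++j)
      if (n_layer[j] != n_layer[0]) return false;
    return true;
  }();

  std::vector<double> paths;
  std::vector<int> out_src, out_det;
  long long n_top_other = 0, n_side = 0, n_bottom = 0, n_cutoff = 0;

  for (int si = 0; si < nsrc; ++si) {
    Xoshiro rng(((uint64_t)(uint32_t)seed << 8) + (uint64_t)(si + 1));

    for (long long k = 0; k < npp; ++k) {
      double x = src_x[si], y = src_y[si], z = 0.0;
      double ux = 0.0, uy = 0.0, uz = 1.0;
      int li = 0;
      std::fill(lp.begin(), lp.end(), 0.0);
      double total = 0.0;
      int fate = -1;
      double exit_x = 0.0, exit_y = 0.0;

      while (fate < 0) {
        double tau = -std::log(rng.u01());  // optical depth of this step

        while (tau > 0.0 && fate < 0) {
          double ztop = (li == 0) ? 0.0 : zbot[li - 1];
          double tb;  // geometric distance to the next z-boundary
          if (uz > 0.0)
            tb = (zbot[li] - z) / uz;
          else if (uz < 0.0)
            tb = (ztop - z) / uz;
          else
            tb = 1e300;
          if (tb < 0.0) tb = 0.0;
          double sgeo = tau / mus[li];

          if (tb > sgeo) {
            x += sgeo * ux; y += sgeo * uy; z += sgeo * uz;
            lp[li] += sgeo; total += sgeo; tau = 0.0;
          } else {
            x += tb * ux; y += tb * uy; z += tb * uz;
            lp[li] += tb; total += tb; tau -= tb * mus[li];
            if (uz < 0.0 && li == 0) {
              z = 0.0;  // top surface: Fresnel reflect or exit
              double R = (n_layer[0] == n_out)
                             ? 0.0
                             : fresnel_unpol(-uz, n_layer[0], n_out);
              if (R > 0.0 && rng.u01() < R) {
                uz = -uz;
              } else {
                fate = 0; exit_x = x; exit_y = y;
              }
            } else if (uz > 0.0 && li == nl - 1) {
              fate = 3;  // bottom escape
            } else {
              int lj = (uz > 0.0) ? li + 1 : li - 1;
              if (uniform_n || n_layer[li] == n_layer[lj]) {
                li = lj;
              } else {
                double R = fresnel_unpol(uz, n_layer[li], n_layer[lj]);
                if (rng.u01() < R) {
                  uz = -uz;
                } else {
                  double sin_i = std::sqrt(std::max(0.0, 1.0 - uz * uz));
                  double sin_t = n_layer[li] / n_layer[lj] * sin_i;
                  double cos_t = std::sqrt(std::max(0.0, 1.0 - sin_t * sin_t));
                  if (sin_i > 1e-12) {
                    double sc = sin_t / sin_i;
                    ux *= sc; uy *= sc;
                  }
                  uz = (uz > 0.0) ? cos_t : -cos_t;
                  double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
                  ux /= nn; uy /= nn; uz /= nn;
                  li = lj;
                }
              }
            }
          }
          if (fate < 0) {
            if (x < xlim[0] || x > xlim[1] || y < ylim[0] || y > ylim[1])
              fate = 2;  // lateral escape
            else if (total > max_path)
              fate = 4;  // cutoff
          }
        }
        if (fate >= 0) break;

        // scatter: isotropic for g = 0, Henyey-Greenstein otherwise
        double gg = g[li];
        if (gg == 0.0) {
          uz = 2.0 * rng.u01() - 1.0;
          double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
          double cp, sp;
          rand_azimuth(rng, cp, sp);
          ux = st * cp; uy = st * sp;
        } else {
          double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.u01());
          double ct = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
          if (ct > 1.0) ct = 1.0;
          if (ct < -1.0) ct = -1.0;
          double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
          double cp, sp;
          rand_azimuth(rng, cp, sp);
          if (std::fabs(uz) > 0.99999) {
            ux = st * cp; uy = st * sp; uz = (uz > 0.0) ? ct : -ct;
          } else {
            double den = std::sqrt(1.0 - uz * uz);
            double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
            double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
            double nuz = -st * cp * den + uz * ct;
            ux = nux; uy = nuy; uz = nuz;
          }
        }
      }

      if (fate == 0) {
        int det = -1;
        if (annular) {
          double dx = exit_x - src_x[si], dy = exit_y - src_y[si];
          double r2 = dx * dx + dy * dy;
          for (int d = 0; d < ndet_t; ++d) {
            if (r2 >= rings(d, 0) * rings(d, 0) &&
                r2 < rings(d, 1) * rings(d, 1)) { det = d; break; }
          }
        } else {
          for (int d = 0; d < ndet_t; ++d) {
            double dx = exit_x - det_xy(d, 0), dy = exit_y - det_xy(d, 1);
            if (dx * dx + dy * dy <= det_radius * det_radius) {
              det = d; break;
            }
          }
        }
        if (det >= 0) {
          for (int j = 0; j < nl; ++j) paths.push_back(lp[j]);
          out_src.push_back(si + 1);
          out_det.push_back(det + 1);
        } else {
          ++n_top_other;
        }
      } else if (fate == 2) {
        ++n_side;
      } else if (fate == 3) {
        ++n_bottom;
      } else {
        ++n_cutoff;
      }
      if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }

  const long long ndet = (long long)out_src.size();
  NumericMatrix pm(ndet, nl);
  for (long long i = 0; i < ndet; ++i)
    for (int j = 0; j < nl; ++j) pm(i, j) = paths[i * nl + j];

  return List::create(
      _["paths"] = pm,
      _["source"] = IntegerVector(out_src.begin(), out_src.end()),
      _["detector"] = IntegerVector(out_det.begin(), out_det.end()),
      _["n_detected"] = (double)ndet, _["n_top_other"] = (double)n_top_other,
      _["n_side"] = (double)n_side, _["n_bottom"] = (double)n_bottom,
      _["n_cutoff"] = (double)n_cutoff);
}
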