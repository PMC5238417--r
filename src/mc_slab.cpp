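// Monte-Carlo photon transport through a turbid slab, with per-photon
// tracking of the pathlength traveled inside an optional spherical region.
//
// Scattering is isotropic at rate mus (set equal to the reduced scattering
// coefficient for validation of time-resolved transmittance). Absorption is
// handled analytically: the photon carries its total pathlength and the
// detection weight is exp(-mua * L), so one run serves any absorption and any
// sphere contrast. Fresnel reflection (unpolarized) applies at both faces.

#include <Rcpp.h>
#include <random>
using namespace Rcpp;

static inline double fresnel_R(double n_in, double n_out, double cosi) {
  // unpolarized Fresnel reflectance for incidence cosine cosi (> 0)
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n_in / n_out * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint * sint);
  double rs = (n_in * cosi - n_out * cost) / (n_in * cosi + n_out * cost);
  double rp = (n_in * cost - n_out * cosi) / (n_in * cost + n_out * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// pathlength of the segment p -> p + step*u inside a sphere (ctr, rad)
static inline double sphere_path(const double p[3], const double u[3],
                                 double step, const double ctr[3],
                                 double rad) {
  double oc[3] = {p[0] - ctr[0], p[1] - ctr[1], p[2] - ctr[2]};
  double b = oc[0] * u[0] + oc[1] * u[1] + oc[2] * u[2];
  double c = oc[0] * oc[0] + oc[1] * oc[1] + oc[2] * oc[2] - rad * rad;
  double disc = b * b - c;
  if (disc <= 0.0) return 0.0;
  double sq = std::sqrt(disc);
  double t0 = -b - sq, t1 = -b + sq;
  double lo = std::max(t0, 0.0), hi = std::min(t1, step);
  return (hi > lo) ? hi - lo : 0.0;
}

// [[Rcpp::export(name = ".mc_slab_cpp")]]
List mc_slab_cpp(double mus, double thickness, double n_in, double n_out,
                 double det_radius, bool has_sphere, NumericVector sphere,
                 double n_photons, int seed, double l_max) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  double ctr[3] = {0, 0, 0};
  double rad = 0;
  if (has_sphere) {
    ctr[0] = sphere[0]; ctr[1] = sphere[1]; ctr[2] = sphere[2];
    rad = sphere[3];
  }

  std::vector<double> out_L, out_Ls;
  const long long N = static_cast<long long>(n_photons);
  out_L.reserve(16384); out_Ls.reserve(16384);

  for (long long i = 0; i < N; ++i) {
    double p[3] = {0, 0, 0};
    double u[3] = {0, 0, 1};       // pencil beam entering at the origin
    double L = 0, Ls = 0;
    bool alive = true;

    while (alive) {
      double step = (mus > 0) ? -std::log(1.0 - unif(rng)) / mus
                              : 2.0 * l_max;
      // boundary crossing?
      double dz = u[2];
      double t_bound = -1;
      int face = 0;                // 1 = exit bottom (z = s), -1 = exit top
      if (dz > 0) {
        double tb = (thickness - p[2]) / dz;
        if (tb <= step) { t_bound = tb; face = 1; }
      } else if (dz < 0) {
        double tb = (0.0 - p[2]) / dz;
        if (tb <= step) { t_bound = tb; face = -1; }
      }

      if (face != 0) {
        // advance to the face
        if (has_sphere) Ls += sphere_path(p, u, t_bound, ctr, rad);
        L += t_bound;
        p[0] += u[0] * t_bound; p[1] += u[1] * t_bound; p[2] += u[2] * t_bound;
        double cosi = std::fabs(u[2]);
        double R = fresnel_R(n_in, n_out, cosi);
        if (unif(rng) < R) {
          u[2] = -u[2];            // specular reflection, stay inside
        } else {
          if (face == 1) {         // transmitted through the exit face
            double r2 = p[0] * p[0] + p[1] * p[1];
            if (!std::isfinite(det_radius) || r2 <= det_radius * det_radius) {
              out_L.push_back(L);
              out_Ls.push_back(Ls);
            }
          }
          alive = false;           // transmitted or lost through entry face
          continue;
        }
      } else {
        if (has_sphere) Ls += sphere_path(p, u, step, ctr, rad);
        L += step;
        p[0] += u[0] * step; p[1] += u[1] * step; p[2] += u[2] * step;
        // isotropic scatter
        double cz = 2.0 * unif(rng) - 1.0;
        double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        double ph = 2.0 * M_PI * unif(rng);
        u[0] = sz * std::cos(ph); u[1] = sz * std::sin(ph); u[2] = cz;
      }
      if (L > l_max) alive = false;
    }
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["L"] = NumericVector(out_L.begin(), out_L.end()),
                      _["Ls"] = NumericVector(out_Ls.begin(), out_Ls.end()),
                      _["n_launched"] = (double)N);
}
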