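#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Deterministic 64-bit generator (splitmix64-seeded xoshiro256+).
// Compiler-independent uniforms: top 53 bits -> (0,1].
namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1]
  inline double u01() {
    return ((next() >> 11) + 1) * 1.1102230246251565e-16;
  }
};

inline double fresnel_unpolarized(double n1, double n2, double cos_i,
                                  double &cos_t) {
  // cos_i > 0; returns reflectance, sets cos_t (transmitted polar cosine)
  if (n1 == n2) { cos_t = cos_i; return 0.0; }
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = (n1 / n2) * (n1 / n2) * sin_i2;
  if (sin_t2 >= 1.0) { cos_t = 0.0; return 1.0; }  // total internal reflection
  cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t);
  double rp = (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// Layered slab photon transport with Henyey-Greenstein scattering and
// unpolarized Fresnel boundaries. Pencil beam at the origin, normal
// incidence. White mode (mua all zero) applies no absorption in flight;
// oracle mode decays the packet weight by exp(-mua * ds) along every
// segment, on the identical random-number stream, so geometric paths match
// the white run photon for photon.
//
// [[Rcpp::export]]
List mc_transport_cpp(NumericVector thickness,  // mm, last entry may be Inf
                      NumericVector mus,        // mm^-1, > 0
                      NumericVector g,
                      NumericVector nidx,       // refractive index per layer
                      double n_ambient,
                      double n_photons,
                      double seed,
                      NumericVector sdd,        // ring centers, mm
                      double radius,            // ring half-width, mm
                      double r_max,
                      double l_max,
                      NumericVector l_layer_max,  // per-layer budgets (Inf = none)
                      NumericVector mua) {      // oracle mode if any > 0
  const int M = thickness.size();
  const int ndet = sdd.size();
  bool oracle = false;
  for (int j = 0; j < M; ++j) if (mua[j] > 0) oracle = true;

  // layer z boundaries: layer j occupies [zb[j], zb[j+1])
  std::vector<double> zb(M + 1);
  zb[0] = 0.0;
  for (int j = 0; j < M; ++j)
    zb[j + 1] = std::isfinite(thickness[j]) ? zb[j] + thickness[j] : INFINITY;

  Rng rng(static_cast<uint64_t>(seed));

  // specular entry loss
  double ct0;
  double r_sp = fresnel_unpolarized(n_ambient, nidx[0], 1.0, ct0);
  double w_launch = 1.0 - r_sp;

  std::vector<std::vector<double>> Lrec(M);
  std::vector<double> wrec, rrec;
  std::vector<int> detrec;
  double top_exit_weight = 0.0;
  long n_top_exit = 0;

  const long N = static_cast<long>(n_photons);
  std::vector<double> L(M);

  for (long ip = 0; ip < N; ++ip) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    double w = w_launch;
    double ltot = 0.0;
    std::fill(L.begin(), L.end(), 0.0);
    bool alive = true;

    double tau = -std::log(rng.u01());  // dimensionless scattering depth
    while (alive) {
      double step = tau / mus[layer];
      // distance to layer boundary along uz
      double db = INFINITY;
      bool going_up = uz < 0.0;
      if (uz > 0.0) db = (zb[layer + 1] - z) / uz;
      else if (uz < 0.0) db = (zb[layer] - z) / uz;  // uz<0 -> positive

      if (step >= db) {
        // move to boundary
        x += ux * db; y += uy * db; z += uz * db;
        L[layer] += db; ltot += db;
        if (oracle) w *= std::exp(-mua[layer] * db);
        tau -= db * mus[layer];
        if (ltot > l_max || L[layer] > l_layer_max[layer] ||
            x * x + y * y > r_max * r_max) { alive = false; break; }

        double n1 = nidx[layer];
        double n2 = going_up ? (layer == 0 ? n_ambient : nidx[layer - 1])
                             : nidx[layer + 1];
        double cos_i = std::fabs(uz);
        double cos_t;
        double R = fresnel_unpolarized(n1, n2, cos_i, cos_t);
        if (rng.u01() < R) {
          uz = -uz;  // reflect, stay in layer
        } else {
          // refract: scale transverse components by n1/n2
          double ratio = n1 / n2;
          ux *= ratio; uy *= ratio;
          uz = (uz > 0 ? cos_t : -cos_t);
          // renormalize (guards rounding)
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
          if (going_up && layer == 0) {
            // escaped the top surface
            n_top_exit++;
            top_exit_weight += w;
            double r = std::sqrt(x * x + y * y);
            int det = -1;
            for (int k = 0; k < ndet; ++k)
              if (std::fabs(r - sdd[k]) <= radius) { det = k; break; }
            if (det >= 0) {
              for (int j = 0; j < M; ++j) Lrec[j].push_back(L[j]);
              wrec.push_back(w);
              rrec.push_back(r);
              detrec.push_back(det + 1);
            }
            alive = false;
          } else {
            layer += going_up ? -1 : 1;
          }
        }
      } else {
        // scatter inside the layer
        x += ux * step; y += uy * step; z += uz * step;
        L[layer] += step; ltot += step;
        if (oracle) w *= std::exp(-mua[layer] * step);
        if (ltot > l_max || L[layer] > l_layer_max[layer] ||
            x * x + y * y > r_max * r_max) { alive = false; break; }

        double gg = g[layer];
        double cos_th;
        if (std::fabs(gg) < 1e-12) {
          cos_th = 2.0 * rng.u01() - 1.0;
        } else {
          double f = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.u01());
          cos_th = (1.0 + gg * gg - f * f) / (2.0 * gg);
          if (cos_th > 1.0) cos_th = 1.0;
          if (cos_th < -1.0) cos_th = -1.0;
        }
        double sin_th = std::sqrt(1.0 - cos_th * cos_th);
        double phi = 2.0 * M_PI * rng.u01();
        double cph = std::cos(phi), sph = std::sin(phi);
        if (std::fabs(uz) > 0.99999) {
          ux = sin_th * cph;
          uy = sin_th * sph;
          uz = cos_th * (uz >= 0 ? 1.0 : -1.0);
        } else {
          double den = std::sqrt(1.0 - uz * uz);
          double nx = sin_th * (ux * uz * cph - uy * sph) / den + ux * cos_th;
          double ny = sin_th * (uy * uz * cph + ux * sph) / den + uy * cos_th;
          double nz = -sin_th * cph * den + uz * cos_th;
          ux = nx; uy = ny; uz = nz;
        }
        tau = -std::log(rng.u01());
      }
    }
  }

  const size_t nrec = wrec.size();
  NumericMatrix Lout(nrec, M);
  for (int j = 0; j < M; ++j)
    for (size_t i = 0; i < nrec; ++i) Lout(i, j) = Lrec[j][i];

  return List::create(
      _["L"] = Lout,
      _["weight"] = NumericVector(wrec.begin(), wrec.end()),
      _["r"] = NumericVector(rrec.begin(), rrec.end()),
      _["detector"] = IntegerVector(detrec.begin(), detrec.end()),
      _["n_top_exit"] = static_cast<double>(n_top_exit),
      _["top_exit_weight"] = top_exit_weight);
}

// Batch white-MC reweighting: intensity per (ring, mu-assignment).
// I[d, a] = (1 / n_launched) * sum_{i in ring d} w_i exp(-sum_j mu[a, j] L[i, j])
//
// [[Rcpp::export]]
NumericMatrix intensity_batch_cpp(NumericMatrix L, NumericVector w,
                                  IntegerVector det, int n_det,
                                  NumericMatrix mu, double n_launched) {
  const int nrec = L.nrow(), M = L.ncol(), A = mu.nrow();
  NumericMatrix out(n_det, A);
  for (int a = 0; a < A; ++a) {
    for (int i = 0; i < nrec; ++i) {
      double e = 0.0;
      for (int j = 0; j < M; ++j) e += mu(a, j) * L(i, j);
      out(det[i] - 1, a) += w[i] * std::exp(-e);
    }
  }
  for (int d = 0; d < n_det; ++d)
    for (int a = 0; a < A; ++a) out(d, a) /= n_launched;
  return out;
}
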