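#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// circular complex Gaussian draw (Box-Muller on R's uniform stream):
// one uniform pair yields the real and imaginary parts jointly
static inline std::complex<double> cgauss(double sd) {
  double u1 = unif_rand();
  while (u1 <= 0.0) u1 = unif_rand();
  double u2 = unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1)) * sd;
  return std::complex<double>(r * std::cos(2.0 * M_PI * u2),
                              r * std::sin(2.0 * M_PI * u2));
}

// Speckle renderer core: per voxel, field = amp * speckle (+ noise per
// repeat). Static voxels share one speckle draw across repeats; dynamic
// voxels (1-based indices `didx`) follow an AR(1) chain with per-voxel
// correlation `rho`. A global per-repeat phase emulates bulk motion.
// Draw order (speckle, then per repeat: innovations, noise) is fixed so the
// output is a pure function of R's RNG state.
// [[Rcpp::export(rng = true)]]
ComplexVector render_speckle_cube(NumericVector amp, IntegerVector didx,
                                  NumericVector rho, NumericVector phases,
                                  double noise_sd, int repeats) {
  const R_xlen_t n = amp.size();
  const R_xlen_t nd = didx.size();
  const double s2 = std::sqrt(0.5);
  ComplexVector out(n * (R_xlen_t)repeats);

  std::vector<std::complex<double>> s(n), cur(nd);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = cgauss(s2);
  for (R_xlen_t j = 0; j < nd; ++j) cur[j] = s[didx[j] - 1];

  for (int r = 0; r < repeats; ++r) {
    if (r > 0) {
      for (R_xlen_t j = 0; j < nd; ++j) {
        double rj = rho[j];
        cur[j] = rj * cur[j] + std::sqrt(1.0 - rj * rj) * cgauss(s2);
        s[didx[j] - 1] = cur[j];
      }
    }
    const std::complex<double> ph =
      std::polar(1.0, phases[r]);
    Rcomplex *slice = &out[(R_xlen_t)r * n];
    if (noise_sd > 0.0) {
      for (R_xlen_t i = 0; i < n; ++i) {
        std::complex<double> v = (amp[i] * s[i] + cgauss(noise_sd)) * ph;
        slice[i].r = v.real(); slice[i].i = v.imag();
      }
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        std::complex<double> v = amp[i] * s[i] * ph;
        slice[i].r = v.real(); slice[i].i = v.imag();
      }
    }
  }
  return out;
}

// Mean |signal|^2 over the repeat axis of a (Z*X*Y, repeats) complex cube.
// [[Rcpp::export(rng = false)]]
NumericVector cube_power_mean(ComplexVector cube, int repeats) {
  const R_xlen_t n = cube.size() / repeats;
  NumericVector out(n);
  for (int r = 0; r < repeats; ++r) {
    const Rcomplex *slice = &cube[(R_xlen_t)r * n];
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] += slice[i].r * slice[i].r + slice[i].i * slice[i].i;
  }
  for (R_xlen_t i = 0; i < n; ++i) out[i] /= repeats;
  return out;
}
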