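#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Overdamped (Euler-Maruyama) Brownian dynamics on a periodic dihedral
// potential, optionally with a harmonic restraint and an early-stop
// threshold for first-passage runs.  Uses an own xoshiro256++ generator
// seeded through splitmix64 so that trajectories are bit-reproducible for
// a given seed, independent of R's RNG state.

namespace {

const double kDeg2Rad = M_PI / 180.0;

struct Xoshiro256pp {
  uint64_t s[4];

  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]
  double runif() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }

  bool have_spare = false;
  double spare = 0.0;

  // standard normal via Box-Muller (deterministic, portable)
  double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// wrap an angle (degrees) into [-90, 270)
inline double wrap_deg(double x) {
  return x - 360.0 * std::floor((x + 90.0) / 360.0);
}

// minimal periodic difference, in [-180, 180)
inline double wrap_diff(double x) {
  return x - 360.0 * std::floor((x + 180.0) / 360.0);
}

// dV/dphi in kcal/mol/deg for terms (n, V, gamma) scaled by alpha
inline double dihedral_grad(const Rcpp::NumericMatrix &terms, double alpha,
                            double phi) {
  double g = 0.0;
  for (int i = 0; i < terms.nrow(); ++i) {
    double n = terms(i, 0), V = terms(i, 1), gam = terms(i, 2);
    g += -alpha * 0.5 * V * n * std::sin((n * phi - gam) * kDeg2Rad) * kDeg2Rad;
  }
  return g;
}

} // namespace

// [[Rcpp::export(name = ".bd_integrate")]]
Rcpp::List bd_integrate(Rcpp::NumericMatrix terms, double alpha,
                        Rcpp::NumericMatrix bg_terms,
                        double omega0, double D, double beta, double dt,
                        double n_steps_d, int save_stride,
                        bool has_restraint, double restraint_ref,
                        double restraint_k,
                        int stop_mode, double stop_threshold,
                        double seed_d) {
  // n_steps and seed passed as doubles to allow > 2^31 from R
  long long n_steps = (long long)n_steps_d;
  uint64_t seed = (uint64_t)seed_d;
  Xoshiro256pp rng(seed);

  double phi = omega0; // unwrapped coordinate
  double noise_amp = std::sqrt(2.0 * D * dt);
  long long n_save = n_steps / save_stride + 2;
  std::vector<double> out_omega; out_omega.reserve((size_t)n_save);
  std::vector<double> out_step; out_step.reserve((size_t)n_save);

  out_omega.push_back(wrap_deg(phi));
  out_step.push_back(0.0);

  long long stopped_at = -1;
  for (long long step = 1; step <= n_steps; ++step) {
    double grad = dihedral_grad(terms, alpha, phi);
    if (bg_terms.nrow() > 0) grad += dihedral_grad(bg_terms, 1.0, phi);
    if (has_restraint)
      grad += restraint_k * wrap_diff(phi - restraint_ref);
    phi += -beta * D * grad * dt + noise_amp * rng.rnorm();

    double w = wrap_deg(phi);
    bool stop = (stop_mode == 1 && w < stop_threshold) ||
                (stop_mode == 2 && w > stop_threshold);
    if (step % save_stride == 0 || stop) {
      out_omega.push_back(w);
      out_step.push_back((double)step);
    }
    if (stop) { stopped_at = step; break; }
  }

  return Rcpp::List::create(
      Rcpp::Named("omega") = Rcpp::NumericVector(out_omega.begin(), out_omega.end()),
      Rcpp::Named("step") = Rcpp::NumericVector(out_step.begin(), out_step.end()),
      Rcpp::Named("stopped_at") = (double)stopped_at,
      Rcpp::Named("final_phi") = phi);
}
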