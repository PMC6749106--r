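#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Weighted coupon-collection cores. Hot loops run ~1e9 iterations at the
// package's default study sizes, so the RNG is a local xoshiro256++ stream
// seeded from R's RNG on the R side (two 31-bit integers per replicate),
// keeping every run reproducible under set.seed() while staying fast.

namespace {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // strictly inside (0, 1): safe for logs
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline uint64_t combine_seed(Rcpp::IntegerVector seed) {
  uint64_t a = static_cast<uint64_t>(static_cast<uint32_t>(seed[0]));
  uint64_t b = static_cast<uint64_t>(static_cast<uint32_t>(seed[1]));
  return (a << 32) ^ b ^ 0xD1B54A32D192ED03ULL;
}

}  // namespace

// Draw reads with replacement from a grouped k-mer population (group g has
// size[g] equiprobable k-mers carrying total mass[g]); record the read index
// at which each ascending distinct-count threshold is first reached.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_simulate_community(Rcpp::NumericVector sizes,
                                           Rcpp::NumericVector masses,
                                           Rcpp::NumericVector target_counts,
                                           double max_reads,
                                           Rcpp::IntegerVector seed) {
  const int ng = sizes.size();
  std::vector<double> cum(ng);
  std::vector<uint64_t> size_u(ng), offset(ng);
  double acc = 0.0;
  uint64_t total = 0;
  for (int g = 0; g < ng; ++g) {
    acc += masses[g];
    cum[g] = acc;
    size_u[g] = static_cast<uint64_t>(sizes[g] + 0.5);
    offset[g] = total;
    total += size_u[g];
  }
  cum[ng - 1] = 1.0;  // guard against rounding in the final bin

  std::vector<uint64_t> bits((total + 63) / 64, 0ULL);
  Xoshiro256 rng(combine_seed(seed));

  const int nt = target_counts.size();
  Rcpp::NumericVector out(nt, NA_REAL);
  int ti = 0;
  uint64_t distinct = 0;
  const uint64_t maxr = static_cast<uint64_t>(max_reads);

  for (uint64_t reads = 1; reads <= maxr; ++reads) {
    if ((reads & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
    const double u = rng.unif();
    int g = 0;
    while (u > cum[g]) ++g;  // ng is small; abundant groups come first
    uint64_t idx = static_cast<uint64_t>(rng.unif() * static_cast<double>(size_u[g]));
    if (idx >= size_u[g]) idx = size_u[g] - 1;
    const uint64_t pos = offset[g] + idx;
    const uint64_t word = pos >> 6;
    const uint64_t bit = 1ULL << (pos & 63);
    if (!(bits[word] & bit)) {
      bits[word] |= bit;
      ++distinct;
      while (ti < nt && static_cast<double>(distinct) >= target_counts[ti]) {
        out[ti] = static_cast<double>(reads);
        ++ti;
      }
      if (ti == nt) break;
    }
  }
  return out;
}

// Number of draws from K equiprobable k-mers (with replacement) needed to
// observe d distinct ones: a sum of d geometric waiting times with success
// probabilities (K - i)/K. Early coupons almost always succeed on the first
// draw (fast path); late, rare coupons use geometric inversion.
// [[Rcpp::export]]
double cpp_coupon_hits(double K, double d, Rcpp::IntegerVector seed) {
  Xoshiro256 rng(combine_seed(seed));
  const uint64_t dd = static_cast<uint64_t>(d);
  double draws = 0.0;
  for (uint64_t i = 0; i < dd; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    const double qfail = static_cast<double>(i) / K;  // P(draw an already-seen k-mer)
    double u = rng.unif();
    if (u > qfail) {
      draws += 1.0;
    } else if (qfail < 0.5) {
      double g = 1.0;
      do {
        g += 1.0;
        u = rng.unif();
      } while (u <= qfail);
      draws += g;
    } else {
      draws += 1.0 + std::floor(std::log(u) / std::log(qfail));
    }
  }
  return draws;
}
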