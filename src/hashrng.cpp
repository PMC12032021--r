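#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Counter-based uniform generator: splitmix64 finaliser applied to a key built
// from (seed, unit id, time index, event channel). Each simulated decision is
// addressed by its key, so paired counterfactual runs that share a seed draw
// the *same* uniform for the same person/time/event regardless of what other
// events occurred — common random numbers without stream bookkeeping.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double key_unif(uint64_t seed, uint64_t a, uint64_t b, uint64_t c) {
  uint64_t h = mix64(seed ^ 0xA3C59AC2ULL);
  h = mix64(h ^ a);
  h = mix64(h ^ (b + 0x1B873593ULL));
  h = mix64(h ^ (c + 0xCC9E2D51ULL));
  // 53 high bits -> double in (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// [[Rcpp::export]]
NumericVector hash_unif_cpp(double seed, NumericVector id, NumericVector t,
                            NumericVector channel) {
  R_xlen_t n = std::max(id.size(), std::max(t.size(), channel.size()));
  if (n == 0 || id.size() == 0 || t.size() == 0 || channel.size() == 0)
    return NumericVector(0);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t a = (uint64_t)(int64_t)id[i % id.size()];
    uint64_t b = (uint64_t)(int64_t)t[i % t.size()];
    uint64_t c = (uint64_t)(int64_t)channel[i % channel.size()];
    out[i] = key_unif((uint64_t)(int64_t)seed, a, b, c);
  }
  return out;
}
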