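#ifndef SPLICECELL_RNG_H
#define SPLICECELL_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256** (Blackman & Vigna, public domain reference construction),
// seeded through splitmix64 from a (seed, stream) pair so that every
// replicate gets an independent, reproducible stream.
class Xoshiro256 {
 public:
  Xoshiro256(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream * 0xBF58476D1CE4E5B9ULL + 1ULL;
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(x);
    // discard a few outputs to decorrelate near-equal seeds
    for (int i = 0; i < 8; ++i) (void)next();
  }

  uint64_t next() {
    const uint64_t result = rotl(s_[1] * 5, 7) * 9;
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // exponential with rate `rate` (> 0)
  double exp_rate(double rate) {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u) / rate;
  }

 private:
  uint64_t s_[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
};

#endif
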