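#ifndef DMCVIB_RNG_H
#define DMCVIB_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding; independent substreams are obtained
// by mixing a stream id into the seed.  Marsaglia polar method for normals.
struct Xoshiro {
  uint64_t s[4];
  bool have_spare;
  double spare;

  static inline uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  Xoshiro(uint64_t seed, uint64_t stream = 0) : have_spare(false), spare(0.0) {
    uint64_t x = seed ^ (0xA3C59AC2ULL + stream * 0xD1B54A32D192ED03ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    for (int i = 0; i < 16; ++i) next();  // warm up
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

#endif
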