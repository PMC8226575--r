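#ifndef COUNTCAST_RNG_H
#define COUNTCAST_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded through splitmix64; Box-Muller normals with a cached
// spare. Seeded per call from R's RNG stream so set.seed() governs everything.
struct Xoshiro {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit Xoshiro(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
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

  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }

  inline double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925287 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

#endif
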