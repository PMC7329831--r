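#ifndef METADBG_KMER_UTIL_H
#define METADBG_KMER_UTIL_H

#include <cstdint>
#include <cstddef>
#include <string>

// 2-bit packed k-mers, k <= 63, in an unsigned 128-bit integer.
// Encoding A=0, C=1, G=2, T=3 makes integer order == lexicographic order.
typedef unsigned __int128 u128;

static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char bit2base(int b) { return "ACGT"[b & 3]; }

static inline u128 kmask(int k) {
    u128 one = 1;
    return (one << (2 * k)) - 1;
}

static inline std::string decode_kmer(u128 code, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bit2base((int)(code & 3));
        code >>= 2;
    }
    return s;
}

static inline uint64_t mix64(uint64_t h) {
    h ^= h >> 30; h *= 0xBF58476D1CE4E5B9ULL;
    h ^= h >> 27; h *= 0x94D049BB133111EBULL;
    h ^= h >> 31;
    return h;
}

struct U128Hash {
    size_t operator()(u128 x) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        return (size_t)mix64(lo ^ mix64(hi + 0x9E3779B97F4A7C15ULL));
    }
};

#endif
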