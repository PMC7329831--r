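#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include "kmer_util.h"

using namespace Rcpp;

// Minimal blocked-free Bloom filter with 3 Kirsch-Mitzenmacher hashes.
// Sized at ~10 bits per expected insertion (FPR around 1-2%); false
// positives only ever promote singletons, which finalization removes, so
// the filter affects memory, never counts.
class Bloom {
    std::vector<uint64_t> bits;
    uint64_t m;
public:
    explicit Bloom(uint64_t n_expected) {
        m = std::max<uint64_t>(1024, n_expected * 10);
        bits.assign((m + 63) / 64, 0);
    }
    inline void hashes(u128 x, uint64_t &h1, uint64_t &h2) const {
        uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
        h1 = mix64(lo ^ mix64(hi));
        h2 = mix64(lo + 0x9E3779B97F4A7C15ULL) | 1;
    }
    bool contains_or_insert(u128 x) {
        uint64_t h1, h2;
        hashes(x, h1, h2);
        bool present = true;
        for (int i = 0; i < 3; ++i) {
            uint64_t idx = (h1 + (uint64_t)i * h2) % m;
            uint64_t word = idx >> 6, bit = 1ULL << (idx & 63);
            if (!(bits[word] & bit)) { present = false; bits[word] |= bit; }
        }
        return present;
    }
};

struct ExtCounts {
    int count;
    int ext[8]; // lA lC lG lT rA rC rG rT, canonical orientation
    ExtCounts() : count(0) { std::fill(ext, ext + 8, 0); }
};

// Enumerate canonical k-mers of one N-free stretch, with flanking bases.
// cb(canon, canon_is_fwd, left_base, left_qual, right_base, right_qual)
// flank base = -1 when outside the stretch.
template <typename F>
static void each_window(const char *seq, const char *qual, int start, int end,
                        int k, F cb) {
    if (end - start < k) return;
    u128 mask = kmask(k);
    u128 fwd = 0, rc = 0;
    int shift = 2 * (k - 1);
    for (int i = start; i < start + k; ++i) {
        int b = base2bit(seq[i]);
        fwd = ((fwd << 2) | (u128)b) & mask;
        rc = (rc >> 2) | ((u128)(3 - b) << shift);
    }
    for (int pos = start; pos + k <= end; ++pos) {
        bool is_fwd = fwd <= rc;
        u128 canon = is_fwd ? fwd : rc;
        int lb = (pos > start) ? base2bit(seq[pos - 1]) : -1;
        int rb = (pos + k < end) ? base2bit(seq[pos + k]) : -1;
        int lq = (lb >= 0 && qual) ? (qual[pos - 1] - 33) : 0;
        int rq = (rb >= 0 && qual) ? (qual[pos + k] - 33) : 0;
        if (is_fwd) cb(canon, true, lb, lq, rb, rq);
        else cb(canon, false, rb >= 0 ? 3 - rb : -1, rq,
                lb >= 0 ? 3 - lb : -1, lq);
        if (pos + k < end) {
            int b = base2bit(seq[pos + k]);
            fwd = ((fwd << 2) | (u128)b) & mask;
            rc = (rc >> 2) | ((u128)(3 - b) << shift);
        }
    }
}

// Iterate maximal N-free stretches of a read.
template <typename F>
static void each_stretch(const std::string &s, F cb) {
    int n = (int)s.size(), i = 0;
    while (i < n) {
        while (i < n && base2bit(s[i]) < 0) ++i;
        int j = i;
        while (j < n && base2bit(s[j]) >= 0) ++j;
        if (j > i) cb(i, j);
        i = j;
    }
}

// Two-pass Bloom-filtered exact k-mer counter with quality-gated
// per-side extension counts. Pass 1 promotes k-mers seen at least twice
// (or Bloom false positives) into the exact table; pass 2 counts promoted
// k-mers exactly and accumulates extension counts for flanking bases with
// Phred >= qual_floor. Records with count < min_count are dropped.
// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector seqs, CharacterVector quals,
                     int k, int qual_floor, int min_count) {
    if (k < 3 || k > 63 || k % 2 == 0)
        stop("k must be odd and in [3, 63]");
    int n = seqs.size();
    bool have_qual = quals.size() == n;

    // size the Bloom filter from the total window count (upper bound on
    // distinct k-mers)
    uint64_t total_windows = 0;
    for (int i = 0; i < n; ++i) {
        int L = LENGTH(STRING_ELT(seqs, i));
        if (L >= k) total_windows += (uint64_t)(L - k + 1);
    }
    Bloom bloom(total_windows);
    std::unordered_map<u128, ExtCounts, U128Hash> table;

    // pass 1: promote k-mers already present in the Bloom filter
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        each_stretch(s, [&](int a, int b) {
            each_window(s.c_str(), (const char *)NULL, a, b, k,
                        [&](u128 canon, bool, int, int, int, int) {
                if (bloom.contains_or_insert(canon)) table[canon];
            });
        });
    }

    // pass 2: exact counts + quality-gated extensions over promoted k-mers
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string q = have_qual ? as<std::string>(quals[i]) : std::string();
        const char *qp = have_qual ? q.c_str() : (const char *)NULL;
        each_stretch(s, [&](int a, int b) {
            each_window(s.c_str(), qp, a, b, k,
                        [&](u128 canon, bool, int lb, int lq, int rb, int rq) {
                auto it = table.find(canon);
                if (it == table.end()) return;
                ExtCounts &e = it->second;
                e.count++;
                if (lb >= 0 && (!have_qual || lq >= qual_floor)) e.ext[lb]++;
                if (rb >= 0 && (!have_qual || rq >= qual_floor)) e.ext[4 + rb]++;
            });
        });
    }

    // finalize: drop sub-min_count records, emit in lexicographic order
    std::vector<u128> keys;
    keys.reserve(table.size());
    for (auto &kv : table)
        if (kv.second.count >= min_count) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());

    size_t m = keys.size();
    CharacterVector kmer(m);
    IntegerVector count(m);
    IntegerMatrix ext(m, 8);
    for (size_t i = 0; i < m; ++i) {
        const ExtCounts &e = table[keys[i]];
        kmer[i] = decode_kmer(keys[i], k);
        count[i] = e.count;
        for (int j = 0; j < 8; ++j) ext(i, j) = e.ext[j];
    }
    return List::create(
        _["kmer"] = kmer, _["count"] = count, _["ext"] = ext,
        _["stats"] = List::create(
            _["instances"] = (double)total_windows,
            _["promoted"] = (double)table.size(),
            _["kept"] = (double)m,
            _["dropped_singleton"] = (double)(table.size() - m)));
}
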