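#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include "kmer_util.h"

using namespace Rcpp;

static inline u128 encode_kmer(const std::string &s) {
    u128 code = 0;
    for (char c : s) code = (code << 2) | (u128)base2bit(c);
    return code;
}

static inline u128 revcomp_code(u128 code, int k) {
    u128 rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (u128)(3 - (int)(code & 3));
        code >>= 2;
    }
    return rc;
}

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
        int b = base2bit(c);
        c = b >= 0 ? bit2base(3 - b) : c;
    }
    return r;
}

struct Table {
    int k;
    const IntegerVector &count;
    const IntegerMatrix &ext;
    std::unordered_map<u128, int, U128Hash> idx;
};

// Extension count of the oriented k-mer (record i stores counts in the
// canonical orientation; when the walk holds the reverse complement,
// sides swap and bases complement).
static inline int ext_count(const Table &t, int i, bool canon_is_fwd,
                            bool right, int base) {
    if (canon_is_fwd) return t.ext(i, (right ? 4 : 0) + base);
    return t.ext(i, (right ? 0 : 4) + (3 - base));
}

static inline int t_hq(int count, double alpha, int floor_) {
    int v = (int)std::ceil(alpha * (double)count);
    return std::max(floor_, v);
}

// Bidirectional de Bruijn traversal over a finalized k-mer table.
// Seeds are taken in lexicographic (= input) order; each walk extends with
// the adaptive threshold t_hq(c) = max(floor, ceil(alpha*c)) applied to the
// count of the k-mer being extended, and stops on FORK (>= 2 qualifying
// extensions), DEADEND (none qualifying, or qualifying k-mer absent from
// the table) or a k-mer already claimed by a contig (USED).
// [[Rcpp::export(name = ".walk_contigs_cpp")]]
DataFrame walk_contigs_cpp(CharacterVector kmers, IntegerVector count,
                           IntegerMatrix ext, double alpha, int floor_) {
    int n = kmers.size();
    if (n == 0)
        return DataFrame::create(
            _["seq"] = CharacterVector(0), _["depth"] = NumericVector(0),
            _["nkmer"] = IntegerVector(0),
            _["left_state"] = CharacterVector(0),
            _["right_state"] = CharacterVector(0),
            _["left_fork"] = CharacterVector(0),
            _["right_fork"] = CharacterVector(0),
            _["stringsAsFactors"] = false);
    int k = LENGTH(STRING_ELT(kmers, 0));
    Table t{k, count, ext, {}};
    std::vector<u128> codes(n);
    for (int i = 0; i < n; ++i) {
        codes[i] = encode_kmer(as<std::string>(kmers[i]));
        t.idx[codes[i]] = i;
    }
    std::vector<char> used(n, 0);
    u128 mask = kmask(k);
    int shift = 2 * (k - 1);

    std::vector<std::string> seqs, lstate, rstate, lfork, rfork;
    std::vector<double> depth;
    std::vector<int> nkmer;

    for (int seed = 0; seed < n; ++seed) {
        if (used[seed]) continue;
        used[seed] = 1;
        std::string mid = as<std::string>(kmers[seed]);
        std::string right_part, left_part_rev;
        long double count_sum = count[seed];
        int nk = 1;

        // walk one direction; dir_right=true extends the 3' side of the
        // current oriented k-mer
        auto walk = [&](bool dir_right, std::string &out_state,
                        std::string &out_fork, std::string &appended) {
            u128 fwd = codes[seed], rc = revcomp_code(fwd, k);
            int cur = seed;
            bool canon_is_fwd = true;
            for (;;) {
                int thr = t_hq(count[cur], alpha, floor_);
                int nq = 0, qb = -1;
                std::string fork_bases;
                for (int b = 0; b < 4; ++b)
                    if (ext_count(t, cur, canon_is_fwd, dir_right, b) >= thr) {
                        ++nq; qb = b; fork_bases += bit2base(b);
                    }
                if (nq == 0) { out_state = "deadend"; return; }
                if (nq >= 2) { out_state = "fork"; out_fork = fork_bases; return; }
                u128 nfwd, nrc;
                if (dir_right) {
                    nfwd = ((fwd << 2) | (u128)qb) & mask;
                    nrc = (rc >> 2) | ((u128)(3 - qb) << shift);
                } else {
                    nfwd = (fwd >> 2) | ((u128)qb << shift);
                    nrc = ((rc << 2) | (u128)(3 - qb)) & mask;
                }
                u128 canon = std::min(nfwd, nrc);
                auto it = t.idx.find(canon);
                if (it == t.idx.end()) { out_state = "deadend"; return; }
                int ni = it->second;
                // reciprocal uniqueness: the next k-mer must point back to
                // the current one as its sole qualifying extension on the
                // incoming side, else it is a junction vertex and the
                // unipath stops here
                {
                    bool n_canon_fwd = (nfwd <= nrc);
                    int thr2 = t_hq(count[ni], alpha, floor_);
                    int back_base = dir_right
                        ? (int)((fwd >> (2 * (k - 1))) & 3)   // S[0]
                        : (int)(fwd & 3);                     // S[k-1]
                    int nq2 = 0;
                    bool back_ok = false;
                    for (int b = 0; b < 4; ++b) {
                        int c2 = ext_count(t, ni, n_canon_fwd, !dir_right, b);
                        if (c2 >= thr2) {
                            ++nq2;
                            if (b == back_base) back_ok = true;
                        }
                    }
                    if (nq2 >= 2 || !back_ok) { out_state = "fork"; out_fork = std::string(1, bit2base(qb)); return; }
                }
                if (used[ni]) { out_state = "used"; return; }
                used[ni] = 1;
                appended += bit2base(qb);
                count_sum += count[ni]; ++nk;
                fwd = nfwd; rc = nrc; cur = ni;
                canon_is_fwd = (nfwd <= nrc);
            }
        };

        std::string rs, rf, ls, lf, radd, ladd;
        walk(true, rs, rf, radd);
        walk(false, ls, lf, ladd);
        std::string seq = std::string(ladd.rbegin(), ladd.rend()) + mid + radd;

        // canonical contig orientation for strand-invariant output
        std::string rcseq = revcomp_str(seq);
        if (rcseq < seq) {
            seq.swap(rcseq);
            std::swap(ls, rs);
            std::swap(lf, rf);
            lf = revcomp_str(lf); rf = revcomp_str(rf);
            std::sort(lf.begin(), lf.end());
            std::sort(rf.begin(), rf.end());
        }
        seqs.push_back(seq);
        depth.push_back((double)(count_sum / nk));
        nkmer.push_back(nk);
        lstate.push_back(ls); rstate.push_back(rs);
        lfork.push_back(lf); rfork.push_back(rf);
    }

    // order by sequence so ids do not depend on seed order
    int m = (int)seqs.size();
    std::vector<int> ord(m);
    for (int i = 0; i < m; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return seqs[a] < seqs[b];
    });
    CharacterVector oseq(m), ols(m), ors(m), olf(m), orf(m);
    NumericVector od(m);
    IntegerVector onk(m);
    for (int i = 0; i < m; ++i) {
        int j = ord[i];
        oseq[i] = seqs[j]; od[i] = depth[j]; onk[i] = nkmer[j];
        ols[i] = lstate[j]; ors[i] = rstate[j];
        olf[i] = lfork[j]; orf[i] = rfork[j];
    }
    return DataFrame::create(
        _["seq"] = oseq, _["depth"] = od, _["nkmer"] = onk,
        _["left_state"] = ols, _["right_state"] = ors,
        _["left_fork"] = olf, _["right_fork"] = orf,
        _["stringsAsFactors"] = false);
}
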