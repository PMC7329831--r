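#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include "kmer_util.h"

using namespace Rcpp;

static std::string revcomp_str2(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
        int b = base2bit(c);
        c = b >= 0 ? bit2base(3 - b) : 'N';
    }
    return r;
}

struct Hit {
    int ref, orient;       // orient 0 = fwd, 1 = rc (of the read)
    int rstart, rend;      // original read coords, 0-based half-open
    int cstart, cend;      // ref coords
    int matches, mm;
    int score() const { return matches - mm; }
};

struct SeedIndex {
    int seed_len;
    std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > pos;
    std::vector<std::string> refs;
};

static void build_index(SeedIndex &ix, const CharacterVector &ref_seqs,
                        int seed_len) {
    ix.seed_len = seed_len;
    int n = ref_seqs.size();
    ix.refs.resize(n);
    uint64_t mask = (seed_len == 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1);
    for (int r = 0; r < n; ++r) {
        ix.refs[r] = as<std::string>(ref_seqs[r]);
        const std::string &s = ix.refs[r];
        uint64_t code = 0;
        int run = 0;
        for (int i = 0; i < (int)s.size(); ++i) {
            int b = base2bit(s[i]);
            if (b < 0) { run = 0; continue; }
            code = ((code << 2) | (uint64_t)b) & mask;
            if (++run >= seed_len)
                ix.pos[code].push_back(std::make_pair(r, i - seed_len + 1));
        }
    }
}

// Ungapped extension of a seed match with a shared mismatch budget
// (right first, then left); alignment is trimmed to end on matches.
static bool extend_hit(const std::string &ref, const std::string &qry,
                       int cpos, int qpos, int seed_len, int max_mm,
                       Hit &out) {
    int cl = (int)ref.size(), ql = (int)qry.size();
    int mm = 0;
    int ce = cpos + seed_len, qe = qpos + seed_len;
    int last_ce = ce, last_qe = qe;
    while (ce < cl && qe < ql) {
        if (ref[ce] == qry[qe] && base2bit(qry[qe]) >= 0) {
            ++ce; ++qe; last_ce = ce; last_qe = qe;
        } else if (mm < max_mm) { ++mm; ++ce; ++qe; }
        else break;
    }
    ce = last_ce; qe = last_qe;
    int cs = cpos, qs = qpos;
    int last_cs = cs, last_qs = qs;
    while (cs > 0 && qs > 0) {
        if (ref[cs - 1] == qry[qs - 1] && base2bit(qry[qs - 1]) >= 0) {
            --cs; --qs; last_cs = cs; last_qs = qs;
        } else if (mm < max_mm) { ++mm; --cs; --qs; }
        else break;
    }
    cs = last_cs; qs = last_qs;
    // recount mismatches inside the trimmed interval
    mm = 0;
    for (int i = 0; i < ce - cs; ++i)
        if (ref[cs + i] != qry[qs + i]) ++mm;
    out.cstart = cs; out.cend = ce;
    out.rstart = qs; out.rend = qe; // query coords; caller converts for rc
    out.matches = (ce - cs) - mm; out.mm = mm;
    return (ce - cs) >= seed_len;
}

// Seed-and-extend ungapped alignment of reads against a set of reference
// sequences (contigs). At most `max_hits` alignments are reported per read:
// the best-scoring one, then the best whose read interval barely overlaps
// it (so a read can splint two contigs). `tied` marks reads whose best
// score is achieved by more than one distinct placement.
// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector ref_seqs, CharacterVector read_seqs,
                          int seed_len, int max_mm, int max_hits) {
    if (seed_len < 8 || seed_len > 32) stop("seed_len must be in [8, 32]");
    SeedIndex ix;
    build_index(ix, ref_seqs, seed_len);
    uint64_t mask = (seed_len == 32) ? ~0ULL
        : ((1ULL << (2 * seed_len)) - 1);
    int stride = std::max(1, seed_len / 2);

    std::vector<int> o_read, o_ref, o_rs, o_re, o_cs, o_ce, o_orient,
        o_matches, o_mm, o_rank;
    std::vector<int> o_tied;

    int nreads = read_seqs.size();
    for (int ri = 0; ri < nreads; ++ri) {
        std::string fwd = as<std::string>(read_seqs[ri]);
        int L = (int)fwd.size();
        if (L < seed_len) continue;
        std::vector<Hit> cands;
        std::unordered_set<uint64_t> seen;
        for (int orient = 0; orient < 2; ++orient) {
            std::string qry = orient ? revcomp_str2(fwd) : fwd;
            std::vector<int> offs;
            for (int off = 0; off + seed_len <= L; off += stride)
                offs.push_back(off);
            if (offs.empty() || offs.back() != L - seed_len)
                offs.push_back(L - seed_len);
            for (int off : offs) {
                uint64_t code = 0;
                bool ok = true;
                for (int i = 0; i < seed_len; ++i) {
                    int b = base2bit(qry[off + i]);
                    if (b < 0) { ok = false; break; }
                    code = ((code << 2) | (uint64_t)b) & mask;
                }
                if (!ok) continue;
                auto it = ix.pos.find(code);
                if (it == ix.pos.end()) continue;
                for (auto &pr : it->second) {
                    Hit h;
                    h.ref = pr.first; h.orient = orient;
                    if (!extend_hit(ix.refs[pr.first], qry, pr.second, off,
                                    seed_len, max_mm, h))
                        continue;
                    if (orient) { // convert query coords to original read
                        int qs = h.rstart, qe = h.rend;
                        h.rstart = L - qe; h.rend = L - qs;
                    }
                    uint64_t key = mix64(((uint64_t)h.ref << 34)
                        ^ ((uint64_t)h.cstart << 3) ^ ((uint64_t)h.orient << 1)
                        ^ mix64((uint64_t)h.rstart));
                    if (seen.insert(key).second) cands.push_back(h);
                }
            }
        }
        if (cands.empty()) continue;
        std::sort(cands.begin(), cands.end(), [](const Hit &a, const Hit &b) {
            if (a.score() != b.score()) return a.score() > b.score();
            if (a.ref != b.ref) return a.ref < b.ref;
            if (a.cstart != b.cstart) return a.cstart < b.cstart;
            return a.orient < b.orient;
        });
        const Hit &best = cands[0];
        bool tied = cands.size() > 1 && cands[1].score() == best.score();
        std::vector<const Hit *> picked;
        picked.push_back(&best);
        if (max_hits >= 2) {
            for (size_t i = 1; i < cands.size(); ++i) {
                const Hit &h = cands[i];
                if (h.ref == best.ref && h.orient == best.orient &&
                    h.cstart == best.cstart) continue;
                int ov = std::min(h.rend, best.rend)
                    - std::max(h.rstart, best.rstart);
                int shorter = std::min(h.rend - h.rstart,
                                       best.rend - best.rstart);
                if (ov <= (int)(0.4 * shorter)) { picked.push_back(&h); break; }
            }
        }
        for (size_t p = 0; p < picked.size(); ++p) {
            const Hit &h = *picked[p];
            o_read.push_back(ri + 1); o_ref.push_back(h.ref + 1);
            o_rs.push_back(h.rstart); o_re.push_back(h.rend);
            o_cs.push_back(h.cstart); o_ce.push_back(h.cend);
            o_orient.push_back(h.orient);
            o_matches.push_back(h.matches); o_mm.push_back(h.mm);
            o_rank.push_back((int)p + 1);
            o_tied.push_back(p == 0 ? (tied ? 1 : 0) : 0);
        }
    }
    return DataFrame::create(
        _["read"] = wrap(o_read), _["ref"] = wrap(o_ref),
        _["rstart"] = wrap(o_rs), _["rend"] = wrap(o_re),
        _["cstart"] = wrap(o_cs), _["cend"] = wrap(o_ce),
        _["orient"] = wrap(o_orient), _["matches"] = wrap(o_matches),
        _["mm"] = wrap(o_mm), _["rank"] = wrap(o_rank),
        _["tied"] = wrap(o_tied), _["stringsAsFactors"] = false);
}
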