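#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <map>
#include <tuple>
#include "seq_util.h"

using namespace Rcpp;

// Seed index over a set of sequences ("subjects": reads or contigs).
// Every seed_len-window of every subject (forward strand, no N) is stored
// as (packed code, subject, offset) in one flat sorted array; lookups use
// binary search.  Maximal exact matches (MEMs) are recovered by exact
// extension from seed hits.  Sampling query seeds at stride
// (min_match_len - seed_len + 1) guarantees every MEM of length >=
// min_match_len contains at least one sampled seed, so recall is complete.
struct SeedIndex {
    int seed_len;
    std::vector<std::string> seqs;
    std::vector<std::tuple<uint64_t, uint32_t, uint32_t>> entries; // code, seq, pos
};

template <typename F>
static void scan_seeds(const std::string &s, int k, F f) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t code = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)c) & mask;
        if (++valid >= k) f(code, (uint32_t)(i - k + 1));
    }
}

// [[Rcpp::export]]
SEXP cpp_build_seed_index(CharacterVector seqs, int seed_len) {
    if (seed_len < 4 || seed_len > 32) stop("seed_len must be in [4, 32]");
    XPtr<SeedIndex> idx(new SeedIndex(), true);
    idx->seed_len = seed_len;
    idx->seqs.reserve(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        idx->seqs.push_back(as<std::string>(seqs[i]));
    size_t total = 0;
    for (auto &s : idx->seqs)
        if ((int)s.size() >= seed_len) total += s.size() - seed_len + 1;
    idx->entries.reserve(total);
    for (uint32_t i = 0; i < idx->seqs.size(); ++i)
        scan_seeds(idx->seqs[i], seed_len, [&](uint64_t code, uint32_t pos) {
            idx->entries.emplace_back(code, i, pos);
        });
    std::sort(idx->entries.begin(), idx->entries.end());
    return idx;
}

// [[Rcpp::export]]
int cpp_seed_index_nseq(SEXP idx_) {
    XPtr<SeedIndex> idx(idx_);
    return (int)idx->seqs.size();
}

// [[Rcpp::export]]
CharacterVector cpp_index_seqs(SEXP idx_, IntegerVector i) {
    XPtr<SeedIndex> idx(idx_);
    CharacterVector out(i.size());
    for (R_xlen_t j = 0; j < i.size(); ++j) {
        int v = i[j];
        if (v < 1 || v > (int)idx->seqs.size()) stop("sequence index out of range");
        out[j] = idx->seqs[v - 1];
    }
    return out;
}

struct Mem { uint32_t seq; uint32_t spos; uint32_t qpos; uint32_t len; char strand; };

static void find_mems_one_strand(const SeedIndex &idx, const std::string &q,
                                 int min_len, char strand, int qlen_orig,
                                 std::set<std::tuple<uint32_t, char, uint32_t, uint32_t>> &seen,
                                 std::vector<Mem> &out) {
    const int k = idx.seed_len;
    if ((int)q.size() < k) return;
    const int stride = std::max(1, min_len - k + 1);
    // sampled query seed starts: 0, stride, ..., plus the final window
    std::vector<int> starts;
    for (int p = 0; p + k <= (int)q.size(); p += stride) starts.push_back(p);
    if (starts.empty() || starts.back() != (int)q.size() - k)
        starts.push_back((int)q.size() - k);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int qp : starts) {
        uint64_t code = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
            int c = base_code(q[qp + j]);
            if (c < 0) { ok = false; break; }
            code = ((code << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(),
                                   std::make_tuple(code, (uint32_t)0, (uint32_t)0));
        for (auto it = lo; it != idx.entries.end() && std::get<0>(*it) == code; ++it) {
            uint32_t si = std::get<1>(*it);
            int sp = (int)std::get<2>(*it);
            const std::string &s = idx.seqs[si];
            // extend the exact match maximally in both directions
            int l = 0;
            while (qp - l - 1 >= 0 && sp - l - 1 >= 0 &&
                   bases_match(q[qp - l - 1], s[sp - l - 1])) ++l;
            int r = k;
            while (qp + r < (int)q.size() && sp + r < (int)s.size() &&
                   bases_match(q[qp + r], s[sp + r])) ++r;
            int len = l + r;
            if (len < min_len) continue;
            uint32_t ms = (uint32_t)(sp - l);      // subject start
            uint32_t mq = (uint32_t)(qp - l);      // start on this strand's q
            // map back to original query coordinates
            uint32_t q0 = (strand == '+') ? mq : (uint32_t)(qlen_orig - (int)mq - len);
            auto key = std::make_tuple(si, strand, ms, q0);
            if (!seen.insert(key).second) continue;
            out.push_back(Mem{si, ms, q0, (uint32_t)len, strand});
        }
    }
}

// Returns plain parallel vectors (not a data.frame) because this sits on
// the walker's hot path; R wrappers assemble frames when needed.
// [[Rcpp::export]]
List cpp_find_mems(SEXP idx_, std::string query, int min_match_len) {
    XPtr<SeedIndex> idx(idx_);
    if (min_match_len < idx->seed_len)
        stop("min_match_len (%d) must be >= index seed_len (%d)",
             min_match_len, idx->seed_len);
    std::set<std::tuple<uint32_t, char, uint32_t, uint32_t>> seen;
    std::vector<Mem> mems;
    find_mems_one_strand(*idx, query, min_match_len, '+', (int)query.size(), seen, mems);
    std::string qrc = revcomp(query);
    find_mems_one_strand(*idx, qrc, min_match_len, '-', (int)query.size(), seen, mems);
    std::sort(mems.begin(), mems.end(), [](const Mem &a, const Mem &b) {
        return std::tie(a.seq, a.qpos, a.spos, a.strand) <
               std::tie(b.seq, b.qpos, b.spos, b.strand);
    });
    int n = (int)mems.size();
    IntegerVector seq(n), spos(n), qpos(n), len(n);
    CharacterVector strand(n);
    for (int i = 0; i < n; ++i) {
        seq[i] = (int)mems[i].seq + 1;
        spos[i] = (int)mems[i].spos;
        qpos[i] = (int)mems[i].qpos;
        len[i] = (int)mems[i].len;
        strand[i] = std::string(1, mems[i].strand);
    }
    return List::create(_["seq"] = seq, _["subject_start"] = spos,
                        _["query_start"] = qpos, _["length"] = len,
                        _["strand"] = strand);
}

// Positions of full-length exact occurrences of each query in the subject,
// both strands.  Used for perfect-pair coverage.
// [[Rcpp::export]]
DataFrame cpp_exact_occurrences(std::string subject, CharacterVector queries) {
    const int k = 16;
    SeedIndex idx;
    idx.seed_len = k;
    idx.seqs.push_back(subject);
    scan_seeds(subject, k, [&](uint64_t code, uint32_t pos) {
        idx.entries.emplace_back(code, 0u, pos);
    });
    std::sort(idx.entries.begin(), idx.entries.end());
    std::vector<int> q_out, p_out;
    std::vector<char> s_out;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
        std::string q0 = as<std::string>(queries[qi]);
        if ((int)q0.size() < k) continue;
        for (int pass = 0; pass < 2; ++pass) {
            std::string q = (pass == 0) ? q0 : revcomp(q0);
            char strand = (pass == 0) ? '+' : '-';
            uint64_t code = 0;
            bool ok = true;
            for (int j = 0; j < k; ++j) {
                int c = base_code(q[j]);
                if (c < 0) { ok = false; break; }
                code = ((code << 2) | (uint64_t)c) & mask;
            }
            if (!ok) continue;
            auto lo = std::lower_bound(idx.entries.begin(), idx.entries.end(),
                                       std::make_tuple(code, (uint32_t)0, (uint32_t)0));
            for (auto it = lo; it != idx.entries.end() && std::get<0>(*it) == code; ++it) {
                int sp = (int)std::get<2>(*it);
                if (sp + (int)q.size() > (int)subject.size()) continue;
                if (subject.compare(sp, q.size(), q) != 0) continue;
                q_out.push_back((int)qi + 1);
                p_out.push_back(sp);
                s_out.push_back(strand);
            }
        }
    }
    CharacterVector strand(s_out.size());
    for (size_t i = 0; i < s_out.size(); ++i) strand[i] = std::string(1, s_out[i]);
    return DataFrame::create(_["query"] = wrap(q_out), _["pos"] = wrap(p_out),
                             _["strand"] = strand, _["stringsAsFactors"] = false);
}

// Best ungapped alignment of each read against each indexed subject
// (contig): seed hits nominate (subject, diagonal) candidates; the full
// read is then projected onto the subject along the diagonal and scored.
// Returns at most one row per (read, subject): the one with most matches.
// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP idx_, CharacterVector reads, int min_anchor) {
    XPtr<SeedIndex> idx(idx_);
    if (min_anchor < idx->seed_len) min_anchor = idx->seed_len;
    const int k = idx->seed_len;
    const int stride = std::max(1, min_anchor - k + 1);
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    std::vector<int> r_out, cs_out, ce_out, m_out, ol_out;
    std::vector<char> st_out;
    std::vector<int> sub_out;
    for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
        std::string r0 = as<std::string>(reads[ri]);
        // best per subject: matches, then longer overlap, then '+' strand
        std::map<uint32_t, std::tuple<int, int, int, int, char>> best; // si -> (matches, ol, cs, ce, strand)
        for (int pass = 0; pass < 2; ++pass) {
            std::string q = (pass == 0) ? r0 : revcomp(r0);
            char strand = (pass == 0) ? '+' : '-';
            if ((int)q.size() < k) continue;
            std::set<std::pair<uint32_t, long long>> tried;
            std::vector<int> starts;
            for (int p = 0; p + k <= (int)q.size(); p += stride) starts.push_back(p);
            if (starts.back() != (int)q.size() - k) starts.push_back((int)q.size() - k);
            for (int qp : starts) {
                uint64_t code = 0;
                bool ok = true;
                for (int j = 0; j < k; ++j) {
                    int c = base_code(q[qp + j]);
                    if (c < 0) { ok = false; break; }
                    code = ((code << 2) | (uint64_t)c) & mask;
                }
                if (!ok) continue;
                auto lo = std::lower_bound(idx->entries.begin(), idx->entries.end(),
                                           std::make_tuple(code, (uint32_t)0, (uint32_t)0));
                for (auto it = lo; it != idx->entries.end() && std::get<0>(*it) == code; ++it) {
                    uint32_t si = std::get<1>(*it);
                    long long diag = (long long)std::get<2>(*it) - qp;
                    if (!tried.insert({si, diag}).second) continue;
                    const std::string &s = idx->seqs[si];
                    int a = (int)std::max(0LL, -diag);
                    int b = (int)std::min((long long)q.size(), (long long)s.size() - diag);
                    if (b - a < k) continue;
                    int matches = 0;
                    for (int t = a; t < b; ++t)
                        if (bases_match(q[t], s[t + diag])) ++matches;
                    int ol = b - a;
                    int cs = (int)(a + diag), ce = (int)(b + diag);
                    auto cur = best.find(si);
                    auto cand = std::make_tuple(matches, ol, cs, ce, strand);
                    if (cur == best.end() ||
                        std::make_pair(matches, ol) >
                            std::make_pair(std::get<0>(cur->second), std::get<1>(cur->second)))
                        best[si] = cand;
                }
            }
        }
        for (auto &kv : best) {
            r_out.push_back((int)ri + 1);
            sub_out.push_back((int)kv.first + 1);
            m_out.push_back(std::get<0>(kv.second));
            ol_out.push_back(std::get<1>(kv.second));
            cs_out.push_back(std::get<2>(kv.second));
            ce_out.push_back(std::get<3>(kv.second));
            st_out.push_back(std::get<4>(kv.second));
        }
    }
    CharacterVector strand(st_out.size());
    for (size_t i = 0; i < st_out.size(); ++i) strand[i] = std::string(1, st_out[i]);
    return DataFrame::create(_["read"] = wrap(r_out), _["seq"] = wrap(sub_out),
                             _["c_start"] = wrap(cs_out), _["c_end"] = wrap(ce_out),
                             _["matches"] = wrap(m_out), _["overlap"] = wrap(ol_out),
                             _["strand"] = strand, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = revcomp(as<std::string>(seqs[i]));
    if (seqs.hasAttribute("names")) out.names() = seqs.names();
    return out;
}
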