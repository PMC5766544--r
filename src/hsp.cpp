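#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <tuple>
#include "seq_util.h"

using namespace Rcpp;

// Ungapped seed-and-extend local aligner (HSP finder).  Exact words of
// word_len shared by query and subject seed an x-drop extension along the
// diagonal; each diagonal remembers how far it has been consumed so an HSP
// is reported once.  Substitution-tolerant, indel-free by design: the
// pipeline's sequences diverge by scattered substitutions.

struct Hsp {
    int qs, qe, ss, se;
    char strand;
    int matches;
};

typedef std::unordered_map<uint64_t, std::vector<int>> WordIndex;

static void hsps_one_strand(const std::string &q, const std::string &s,
                            const WordIndex &index,
                            int w, int min_len, double min_ident, int xdrop,
                            char strand, int qlen_orig, std::vector<Hsp> &out) {
    if ((int)q.size() < w) return;
    const uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
    std::unordered_map<long long, int> covered; // diag -> q-end consumed
    uint64_t code = 0;
    int valid = 0;
    for (int qp = 0; qp < (int)q.size(); ++qp) {
        int c = base_code(q[qp]);
        if (c < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)c) & mask;
        if (++valid < w) continue;
        int q0 = qp - w + 1;
        auto bucket = index.find(code);
        if (bucket == index.end()) continue;
        for (int sp : bucket->second) {
            long long d = (long long)sp - q0;
            auto cv = covered.find(d);
            if (cv != covered.end() && q0 < cv->second) continue;
            // extend right from the end of the word
            int best_r = 0, score = 0, best_score = 0;
            int i = q0 + w, j = sp + w;
            while (i < (int)q.size() && j < (int)s.size()) {
                score += bases_match(q[i], s[j]) ? 1 : -2;
                ++i; ++j;
                if (score > best_score) { best_score = score; best_r = i - (q0 + w); }
                if (score < best_score - xdrop) break;
            }
            // extend left from the start of the word
            int best_l = 0;
            score = 0; best_score = 0;
            i = q0 - 1; j = sp - 1;
            while (i >= 0 && j >= 0) {
                score += bases_match(q[i], s[j]) ? 1 : -2;
                --i; --j;
                if (score > best_score) { best_score = score; best_l = (q0 - 1) - i; }
                if (score < best_score - xdrop) break;
            }
            int qs = q0 - best_l, qe = q0 + w + best_r;
            int ss = sp - best_l, se = sp + w + best_r;
            int len = qe - qs;
            int &cov = covered[d];
            cov = std::max(cov, qe);
            if (len < min_len) continue;
            int matches = 0;
            for (int t = 0; t < len; ++t)
                if (bases_match(q[qs + t], s[ss + t])) ++matches;
            if ((double)matches / len < min_ident) continue;
            Hsp h;
            h.strand = strand;
            h.ss = ss; h.se = se; h.matches = matches;
            if (strand == '+') { h.qs = qs; h.qe = qe; }
            else { h.qs = qlen_orig - qe; h.qe = qlen_orig - qs; }
            out.push_back(h);
        }
    }
}

// [[Rcpp::export]]
DataFrame cpp_find_hsps(std::string query, std::string subject, int word_len,
                        int min_len, double min_ident, int xdrop,
                        bool both_strands) {
    if (word_len < 4 || word_len > 32) stop("word_len must be in [4, 32]");
    WordIndex index;
    if ((int)subject.size() >= word_len) {
        index.reserve(subject.size());
        const uint64_t mask = (word_len == 32) ? ~0ULL : ((1ULL << (2 * word_len)) - 1);
        uint64_t code = 0;
        int valid = 0;
        for (int i = 0; i < (int)subject.size(); ++i) {
            int c = base_code(subject[i]);
            if (c < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint64_t)c) & mask;
            if (++valid >= word_len)
                index[code].push_back(i - word_len + 1);
        }
    }
    std::vector<Hsp> out;
    hsps_one_strand(query, subject, index, word_len, min_len, min_ident, xdrop,
                    '+', (int)query.size(), out);
    if (both_strands) {
        std::string qrc = revcomp(query);
        hsps_one_strand(qrc, subject, index, word_len, min_len, min_ident, xdrop,
                        '-', (int)query.size(), out);
    }
    std::sort(out.begin(), out.end(), [](const Hsp &a, const Hsp &b) {
        int sa = 2 * a.matches - (a.qe - a.qs), sb = 2 * b.matches - (b.qe - b.qs);
        if (sa != sb) return sa > sb; // best score first
        return std::tie(a.qs, a.ss, a.strand) < std::tie(b.qs, b.ss, b.strand);
    });
    int n = (int)out.size();
    IntegerVector qs(n), qe(n), ss(n), se(n), len(n), matches(n), score(n);
    NumericVector ident(n);
    CharacterVector strand(n);
    for (int i = 0; i < n; ++i) {
        const Hsp &h = out[i];
        qs[i] = h.qs; qe[i] = h.qe; ss[i] = h.ss; se[i] = h.se;
        len[i] = h.qe - h.qs;
        matches[i] = h.matches;
        ident[i] = (double)h.matches / (h.qe - h.qs);
        score[i] = 2 * h.matches - (h.qe - h.qs);
        strand[i] = std::string(1, h.strand);
    }
    return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                             _["s_start"] = ss, _["s_end"] = se,
                             _["length"] = len, _["matches"] = matches,
                             _["ident"] = ident, _["score"] = score,
                             _["strand"] = strand, _["stringsAsFactors"] = false);
}
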