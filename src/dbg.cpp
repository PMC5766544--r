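#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "seq_util.h"

using namespace Rcpp;

// Canonical de Bruijn unitigger.  Nodes are canonical k-mers; a
// node-orientation is the k-mer string as walked.  Unitigs are maximal
// non-branching paths.  k-mers below min_count are dropped before path
// construction; short dead-end unitigs (tips) can be clipped.

typedef std::unordered_set<std::string> KSet;

static std::string canon(const std::string &s) {
    std::string rc = revcomp(s);
    return std::min(s, rc);
}

static int out_neighbors(const KSet &S, const std::string &s, std::string *first) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = 0;
    std::string t = s.substr(1) + "A";
    for (int i = 0; i < 4; ++i) {
        t[t.size() - 1] = bases[i];
        if (S.count(canon(t))) {
            if (n == 0 && first) *first = t;
            ++n;
        }
    }
    return n;
}

static int in_neighbors(const KSet &S, const std::string &s, std::string *first) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = 0;
    std::string t = "A" + s.substr(0, s.size() - 1);
    for (int i = 0; i < 4; ++i) {
        t[0] = bases[i];
        if (S.count(canon(t))) {
            if (n == 0 && first) *first = t;
            ++n;
        }
    }
    return n;
}

struct Unitig {
    std::string seq;
    std::string first_kmer, last_kmer; // oriented as seq
    std::vector<std::string> keys;     // canonical member k-mers
};

static bool is_start(const KSet &S, const std::string &s) {
    std::string pred;
    int ind = in_neighbors(S, s, &pred);
    if (ind != 1) return true;
    return out_neighbors(S, pred, nullptr) != 1;
}

static std::vector<Unitig> compute_unitigs(const KSet &S) {
    std::vector<std::string> keys(S.begin(), S.end());
    std::sort(keys.begin(), keys.end());
    KSet visited;
    std::vector<Unitig> out;
    auto walk = [&](const std::string &start) {
        Unitig u;
        u.seq = start;
        u.first_kmer = start;
        u.keys.push_back(canon(start));
        visited.insert(canon(start));
        std::string cur = start;
        for (;;) {
            std::string nxt;
            if (out_neighbors(S, cur, &nxt) != 1) break;
            if (in_neighbors(S, nxt, nullptr) != 1) break;
            if (visited.count(canon(nxt))) break; // cycle closure
            u.seq += nxt[nxt.size() - 1];
            u.keys.push_back(canon(nxt));
            visited.insert(canon(nxt));
            cur = nxt;
        }
        u.last_kmer = cur;
        out.push_back(std::move(u));
    };
    for (const auto &key : keys) {
        if (visited.count(key)) continue;
        std::string rc = revcomp(key);
        if (is_start(S, key)) walk(key);
        else if (is_start(S, rc)) walk(rc);
    }
    // leftovers are pure cycles
    for (const auto &key : keys) {
        if (!visited.count(key)) walk(key);
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_dbg_unitigs(CharacterVector reads, int k, int min_count,
                                bool clip_tips) {
    if (k < 3 || k % 2 == 0) stop("k must be odd and >= 3");
    std::unordered_map<std::string, int> counts;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        if ((int)s.size() < k) continue;
        for (size_t p = 0; p + k <= s.size(); ++p) {
            std::string w = s.substr(p, k);
            bool ok = true;
            for (char c : w) if (base_code(c) < 0) { ok = false; break; }
            if (ok) counts[canon(w)]++;
        }
    }
    KSet S;
    for (auto &kv : counts)
        if (kv.second >= min_count) S.insert(kv.first);

    std::vector<Unitig> unitigs = compute_unitigs(S);
    if (clip_tips) {
        for (int round = 0; round < 5; ++round) {
            bool removed = false;
            for (const auto &u : unitigs) {
                if ((int)u.seq.size() >= 2 * k) continue;
                bool dl = in_neighbors(S, u.first_kmer, nullptr) == 0;
                bool dr = out_neighbors(S, u.last_kmer, nullptr) == 0;
                if (dl != dr) { // dangling on exactly one side: a tip
                    for (const auto &key : u.keys) S.erase(key);
                    removed = true;
                }
            }
            if (!removed) break;
            unitigs = compute_unitigs(S);
        }
    }
    std::vector<std::string> seqs;
    seqs.reserve(unitigs.size());
    for (auto &u : unitigs) {
        std::string rc = revcomp(u.seq);
        seqs.push_back(std::min(u.seq, rc));
    }
    std::sort(seqs.begin(), seqs.end());
    seqs.erase(std::unique(seqs.begin(), seqs.end()), seqs.end());
    return wrap(seqs);
}
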