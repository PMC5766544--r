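#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include "seq_util.h"

using namespace Rcpp;

// Exact canonical k-mer counter (k <= 32 so a k-mer packs into 64 bits).
// Canonical form = min(kmer, revcomp(kmer)) on the 2-bit encoding, which
// coincides with the lexicographic minimum because A<C<G<T in both orders.
struct KmerTable {
    int k;
    std::unordered_map<uint64_t, uint32_t> counts;
};

// Rolling scan of one sequence; windows containing non-ACGT contribute
// nothing.  Calls f(canonical_code) for every valid window.
template <typename F>
static void scan_kmers(const std::string &s, int k, F f) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        if (++valid >= k) f(std::min(fwd, rev));
    }
}

static std::string decode_kmer(uint64_t code, int k) {
    static const char *b = "ACGT";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) { s[i] = b[code & 3]; code >>= 2; }
    return s;
}

// [[Rcpp::export]]
SEXP cpp_kmer_table_build(CharacterVector seqs, int k) {
    if (k < 1 || k > 32) stop("k must be in [1, 32] for the exact counter");
    XPtr<KmerTable> tab(new KmerTable(), true);
    tab->k = k;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        scan_kmers(s, k, [&](uint64_t code) { tab->counts[code]++; });
    }
    return tab;
}

// [[Rcpp::export]]
double cpp_kmer_table_size(SEXP tab_) {
    XPtr<KmerTable> tab(tab_);
    return (double)tab->counts.size();
}

// Counts for explicit k-mer strings (canonicalized); k-mer with N -> NA.
// [[Rcpp::export]]
IntegerVector cpp_kmer_table_query(SEXP tab_, CharacterVector kmers) {
    XPtr<KmerTable> tab(tab_);
    int k = tab->k;
    IntegerVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        if ((int)s.size() != k) stop("k-mer %d has length %d, expected %d",
                                     (int)i + 1, (int)s.size(), k);
        int n_seen = 0;
        uint32_t cnt = 0;
        scan_kmers(s, k, [&](uint64_t code) {
            auto it = tab->counts.find(code);
            cnt = (it == tab->counts.end()) ? 0 : it->second;
            ++n_seen;
        });
        out[i] = (n_seen == 1) ? (int)cnt : NA_INTEGER;
    }
    return out;
}

// Full dump for small tables (tests / inspection).
// [[Rcpp::export]]
DataFrame cpp_kmer_table_dump(SEXP tab_) {
    XPtr<KmerTable> tab(tab_);
    std::vector<std::pair<uint64_t, uint32_t>> v(tab->counts.begin(), tab->counts.end());
    std::sort(v.begin(), v.end());
    CharacterVector kmer(v.size());
    IntegerVector count(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        kmer[i] = decode_kmer(v[i].first, tab->k);
        count[i] = (int)v[i].second;
    }
    return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                             _["stringsAsFactors"] = false);
}

// Per-read median k-mer coverage: the lower median of the counts of all
// k-length windows of the read.  Windows containing N contribute count 0.
// Reads shorter than k -> NA ("uncounted").
// [[Rcpp::export]]
IntegerVector cpp_median_kmer_coverage(CharacterVector seqs, SEXP tab_) {
    XPtr<KmerTable> tab(tab_);
    int k = tab->k;
    IntegerVector out(seqs.size());
    std::vector<uint32_t> cov;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        int n_win = (int)s.size() - k + 1;
        if (n_win < 1) { out[i] = NA_INTEGER; continue; }
        cov.assign(n_win, 0);
        // fill counts of valid windows; invalid windows stay 0
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (size_t j = 0; j < s.size(); ++j) {
            int c = base_code(s[j]);
            if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
            if (++valid >= k) {
                auto it = tab->counts.find(std::min(fwd, rev));
                if (it != tab->counts.end()) cov[j - k + 1] = it->second;
            }
        }
        std::sort(cov.begin(), cov.end());
        out[i] = (int)cov[(cov.size() - 1) / 2]; // lower median
    }
    return out;
}

// Lexicographically canonical k-mer strings (min of k-mer and revcomp);
// NA for k-mers containing non-ACGT characters.
// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector kmers) {
    CharacterVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        bool ok = true;
        for (char c : s) if (base_code(c) < 0) { ok = false; break; }
        if (!ok) { out[i] = NA_STRING; continue; }
        std::string rc = revcomp(s);
        out[i] = std::min(s, rc);
    }
    return out;
}
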