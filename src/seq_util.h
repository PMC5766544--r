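#ifndef GENEWALKER_SEQ_UTIL_H
#define GENEWALKER_SEQ_UTIL_H

#include <string>
#include <cstdint>

// 2-bit base codes; anything outside {A,C,G,T} (notably N) is -1.
inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
    default:  return 'N';
    }
}

inline std::string revcomp(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = comp_base(s[i]);
    return out;
}

// Bases never match through N: exactness means unambiguous equality.
inline bool bases_match(char a, char b) {
    return a == b && a != 'N';
}

#endif
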