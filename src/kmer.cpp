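#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else breaks the rolling window.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Histogram of canonical k-mer multiplicities over a set of sequences.
// Canonical form = lexicographic min of the k-mer and its reverse complement
// under the A<C<G<T order, which the 2-bit encoding preserves.
// [[Rcpp::export]]
DataFrame kmer_hist_cpp(CharacterVector seqs, int k) {
    if (k < 1 || k > 31) stop("k must be between 1 and 31");
    std::unordered_map<uint64_t, uint32_t> counts;
    counts.reserve(1 << 20);
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    const int shift = 2 * (k - 1);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        SEXP s = STRING_ELT(seqs, i);
        if (s == NA_STRING) continue;
        const char* p = CHAR(s);
        const int len = LENGTH(s);
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (int j = 0; j < len; ++j) {
            const int c = base_code(p[j]);
            if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
            if (valid < k) ++valid;
            if (valid >= k) {
                const uint64_t canon = fwd < rev ? fwd : rev;
                ++counts[canon];
            }
        }
    }
    std::unordered_map<uint32_t, double> hist;
    for (const auto& kv : counts) hist[kv.second] += 1.0;
    std::vector<uint32_t> mult;
    mult.reserve(hist.size());
    for (const auto& kv : hist) mult.push_back(kv.first);
    std::sort(mult.begin(), mult.end());
    IntegerVector m(mult.size());
    NumericVector n(mult.size());
    for (size_t i = 0; i < mult.size(); ++i) {
        m[i] = (int)mult[i];
        n[i] = hist[mult[i]];
    }
    return DataFrame::create(_["multiplicity"] = m, _["count"] = n);
}
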