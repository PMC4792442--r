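#include <Rcpp.h>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Ungapped scan of an adapter against a read over every offset, including
// partial overhangs at both read ends. A read is flagged when some offset
// aligns >= min_match positions with <= max_mismatch mismatches ('N' counts
// as a mismatch).
// [[Rcpp::export]]
LogicalVector adapter_scan_cpp(CharacterVector reads, std::string adapter,
                               int min_match, int max_mismatch) {
    const int alen = (int)adapter.size();
    LogicalVector out(reads.size());
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        SEXP s = STRING_ELT(reads, i);
        if (s == NA_STRING) { out[i] = NA_LOGICAL; continue; }
        const char* r = CHAR(s);
        const int rlen = LENGTH(s);
        bool hit = false;
        // offset = position of adapter[0] relative to read[0]
        for (int off = -(alen - 1); off <= rlen - 1 && !hit; ++off) {
            const int lo = std::max(0, off);
            const int hi = std::min(rlen, off + alen);  // exclusive
            const int aligned = hi - lo;
            if (aligned < min_match) continue;
            int mm = 0;
            for (int p = lo; p < hi; ++p) {
                const char rb = r[p], ab = adapter[p - off];
                if (rb != ab || rb == 'N' || rb == 'n') ++mm;
                if (mm > max_mismatch) break;
            }
            if (mm <= max_mismatch) hit = true;
        }
        out[i] = hit;
    }
    return out;
}

// Detect mate overlap: slide the reverse complement of mate 2 against mate 1
// the way a short-insert fragment dictates (suffix of read 1 against prefix
// of revcomp(read 2)). Flag when some overlap length >= min_overlap has
// mismatch fraction <= max_mismatch_frac.
// [[Rcpp::export]]
LogicalVector overlap_scan_cpp(CharacterVector seq1, CharacterVector rc2,
                               int min_overlap, double max_mismatch_frac) {
    if (seq1.size() != rc2.size()) stop("mate vectors differ in length");
    LogicalVector out(seq1.size());
    for (R_xlen_t i = 0; i < seq1.size(); ++i) {
        SEXP a = STRING_ELT(seq1, i), b = STRING_ELT(rc2, i);
        if (a == NA_STRING || b == NA_STRING) { out[i] = NA_LOGICAL; continue; }
        const char* s1 = CHAR(a);
        const char* s2 = CHAR(b);
        const int l1 = LENGTH(a), l2 = LENGTH(b);
        const int omax = std::min(l1, l2);
        bool hit = false;
        for (int o = min_overlap; o <= omax && !hit; ++o) {
            const int allowed = (int)std::floor(max_mismatch_frac * o + 1e-9);
            int mm = 0;
            const char* p1 = s1 + (l1 - o);
            for (int j = 0; j < o; ++j) {
                if (p1[j] != s2[j]) ++mm;
                if (mm > allowed) break;
            }
            if (mm <= allowed) hit = true;
        }
        out[i] = hit;
    }
    return out;
}

// Mismatch count between equal-length strings (helper for read placement).
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
    if (a.size() != b.size()) stop("vectors differ in length");
    IntegerVector out(a.size());
    for (R_xlen_t i = 0; i < a.size(); ++i) {
        SEXP x = STRING_ELT(a, i), y = STRING_ELT(b, i);
        if (x == NA_STRING || y == NA_STRING) { out[i] = NA_INTEGER; continue; }
        if (LENGTH(x) != LENGTH(y)) stop("strings differ in length");
        const char* p = CHAR(x);
        const char* q = CHAR(y);
        int mm = 0;
        for (int j = 0; j < LENGTH(x); ++j) if (p[j] != q[j]) ++mm;
        out[i] = mm;
    }
    return out;
}
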