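#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base code; -1 for anything that is not A/C/G/T
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Canonical k-mer multiplicity histogram over a set of reads.
// Each k-mer is pooled with its reverse complement under the numerically
// smaller 2-bit encoding (equivalent to lexicographic order on ACGT).
// K-mers containing non-ACGT characters are skipped; k <= 32.
// [[Rcpp::export]]
List kmer_hist_cpp(CharacterVector reads, int k) {
    if (k < 1 || k > 32) stop("kmer_hist_cpp: k must be in 1..32");
    std::unordered_map<uint64_t, uint32_t> counts;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift_rc = 2 * (k - 1);
    double total_instances = 0.0;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        uint64_t fwd = 0, rc = 0;
        int run = 0;
        for (const char *p = s; *p; ++p) {
            int c = base_code(*p);
            if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)c) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
            if (++run >= k) {
                uint64_t canon = fwd < rc ? fwd : rc;
                ++counts[canon];
                total_instances += 1.0;
            }
        }
    }
    std::unordered_map<uint32_t, double> hist;
    for (const auto &kv : counts) hist[kv.second] += 1.0;
    IntegerVector mult(hist.size());
    NumericVector cnt(hist.size());
    R_xlen_t i = 0;
    for (const auto &kv : hist) {
        mult[i] = (int)kv.first;
        cnt[i] = kv.second;
        ++i;
    }
    return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                        _["total_instances"] = total_instances,
                        _["n_distinct"] = (double)counts.size());
}

// Needleman-Wunsch global alignment, linear gap penalty, deterministic
// traceback preferring diagonal, then up (gap in b), then left (gap in a).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, int match, int mismatch,
                  int gap) {
    const int n = (int)a.size(), m = (int)b.size();
    std::vector<int> score((size_t)(n + 1) * (m + 1));
    auto S = [&](int i, int j) -> int & {
        return score[(size_t)i * (m + 1) + j];
    };
    for (int i = 0; i <= n; ++i) S(i, 0) = i * gap;
    for (int j = 0; j <= m; ++j) S(0, j) = j * gap;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int sub = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
            int up = S(i - 1, j) + gap;
            int left = S(i, j - 1) + gap;
            int best = sub >= up ? sub : up;
            if (left > best) best = left;
            S(i, j) = best;
        }
    }
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            S(i, j) == S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
            ra.push_back(a[i - 1]); rb.push_back('-'); --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = S(n, m));
}

// 0-based start positions where `query` matches `subject` with at most
// max_mm mismatches (full-length, no indels; case-sensitive).
// [[Rcpp::export]]
IntegerVector find_matches_cpp(std::string subject, std::string query,
                               int max_mm) {
    const int n = (int)subject.size(), q = (int)query.size();
    std::vector<int> hits;
    for (int i = 0; i + q <= n; ++i) {
        int mm = 0;
        for (int j = 0; j < q; ++j) {
            if (subject[i + j] != query[j] && ++mm > max_mm) break;
        }
        if (mm <= max_mm) hits.push_back(i);
    }
    return wrap(hits);
}
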