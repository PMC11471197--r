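#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// An 'N' in a read never matches any probe base; probes are validated
// upstream to contain only ACGT.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'a': return 'T';
    case 'C': return 'G'; case 'c': return 'G';
    case 'G': return 'C'; case 'g': return 'C';
    case 'T': return 'A'; case 't': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
    return r;
}

// Precomputed bit masks for one probe (L <= 64).
struct ProbeMasks {
    uint64_t mask[5];
    int L;
    explicit ProbeMasks(const std::string& p) {
        L = (int)p.size();
        for (int b = 0; b < 5; ++b) mask[b] = 0;
        for (int i = 0; i < L; ++i) {
            int c = base_code(p[i]);
            if (c < 4) mask[c] |= (uint64_t)1 << i;
            // probe 'N' matches nothing: no mask bit set
        }
    }
};

// End-position window implementing a minimum read flank on each side of the
// probe split point: an occurrence ending at 0-based read index e spans the
// split at read position e - (L - split); left flank = e - L + 1 + split,
// right flank = n - 1 - e + (L - split).
static inline void flank_window(int n, int L, int split, int min_flank,
                                int& e_lo, int& e_hi) {
    e_lo = L - 1;
    e_hi = n - 1;
    if (min_flank > 0) {
        int lo2 = min_flank - split + L - 1;
        int hi2 = n - 1 - min_flank + (L - split);
        if (lo2 > e_lo) e_lo = lo2;
        if (hi2 < e_hi) e_hi = hi2;
    }
}

// ---- bitap, Hamming model -------------------------------------------------
// Counts alignment end positions (equivalently offsets) where the probe
// matches a length-L substring of the read with <= k substitutions.
static int bitap_hamming(const ProbeMasks& pm, const std::string& read,
                         int k, int split, int min_flank) {
    const int L = pm.L, n = (int)read.size();
    if (n < L) return 0;
    int e_lo, e_hi;
    flank_window(n, L, split, min_flank, e_lo, e_hi);
    if (e_lo > e_hi) return 0;
    std::vector<uint64_t> R(k + 1, 0), Rn(k + 1, 0);
    const uint64_t accept = (uint64_t)1 << (L - 1);
    int count = 0;
    for (int e = 0; e < n; ++e) {
        const uint64_t m = pm.mask[base_code(read[e])];
        Rn[0] = ((R[0] << 1) | 1) & m;
        for (int j = 1; j <= k; ++j)
            Rn[j] = (((R[j] << 1) | 1) & m) | ((R[j - 1] << 1) | 1);
        std::swap(R, Rn);
        if ((R[k] & accept) && e >= e_lo && e <= e_hi) ++count;
    }
    return count;
}

// ---- bitap, edit-distance model (Wu-Manber) -------------------------------
// Counts end positions e where some read substring ending at e is within
// edit distance <= k of the probe (insert/delete/substitute automata).
static int bitap_edit(const ProbeMasks& pm, const std::string& read,
                      int k, int split, int min_flank) {
    const int L = pm.L, n = (int)read.size();
    int e_lo, e_hi;
    flank_window(n, L, split, min_flank, e_lo, e_hi);
    // edit model can end earlier/later than L-1; keep natural bounds
    if (e_lo < 0) e_lo = 0;
    if (e_hi > n - 1) e_hi = n - 1;
    if (e_lo > e_hi || n == 0) return 0;
    std::vector<uint64_t> R(k + 1), Rn(k + 1);
    for (int j = 0; j <= k; ++j)
        R[j] = (j == 0) ? 0 : (((uint64_t)1 << j) - 1);
    const uint64_t accept = (uint64_t)1 << (L - 1);
    int count = 0;
    for (int e = 0; e < n; ++e) {
        const uint64_t m = pm.mask[base_code(read[e])];
        Rn[0] = ((R[0] << 1) | 1) & m;
        for (int j = 1; j <= k; ++j) {
            Rn[j] = (((R[j] << 1) | 1) & m)   // match
                | ((R[j - 1] << 1) | 1)        // substitution
                | R[j - 1]                     // insertion into probe (extra read base)
                | ((Rn[j - 1] << 1) | 1);      // deletion from probe
        }
        std::swap(R, Rn);
        if ((R[k] & accept) && e >= e_lo && e <= e_hi) ++count;
    }
    return count;
}

// ---- naive oracles --------------------------------------------------------
// Independent brute-force implementations used for verification; they share
// no machinery with the bitap path beyond base coding.
static int naive_hamming(const std::string& p, const std::string& read,
                         int k, int split, int min_flank) {
    const int L = (int)p.size(), n = (int)read.size();
    if (n < L) return 0;
    int e_lo, e_hi;
    flank_window(n, L, split, min_flank, e_lo, e_hi);
    int count = 0;
    for (int o = 0; o + L <= n; ++o) {
        int e = o + L - 1;
        if (e < e_lo || e > e_hi) continue;
        int mm = 0;
        for (int i = 0; i < L && mm <= k; ++i) {
            int cp = base_code(p[i]), cr = base_code(read[o + i]);
            if (cp >= 4 || cr >= 4 || cp != cr) ++mm;
        }
        if (mm <= k) ++count;
    }
    return count;
}

// Semi-global DP: D[i] = min edit distance between probe[1..i] and some read
// substring ending at the current position (free start).
static int naive_edit(const std::string& p, const std::string& read,
                      int k, int split, int min_flank) {
    const int L = (int)p.size(), n = (int)read.size();
    int e_lo, e_hi;
    flank_window(n, L, split, min_flank, e_lo, e_hi);
    if (e_lo < 0) e_lo = 0;
    if (e_hi > n - 1) e_hi = n - 1;
    if (n == 0 || e_lo > e_hi) return 0;
    std::vector<int> D(L + 1), Dn(L + 1);
    for (int i = 0; i <= L; ++i) D[i] = i;
    int count = 0;
    for (int e = 0; e < n; ++e) {
        Dn[0] = 0;
        int cr = base_code(read[e]);
        for (int i = 1; i <= L; ++i) {
            int cp = base_code(p[i - 1]);
            int sub = D[i - 1] + ((cp >= 4 || cr >= 4 || cp != cr) ? 1 : 0);
            int del = D[i] + 1;      // skip probe char? no: insert read char
            int ins = Dn[i - 1] + 1; // delete probe char
            int best = sub;
            if (del < best) best = del;
            if (ins < best) best = ins;
            Dn[i] = best;
        }
        std::swap(D, Dn);
        if (D[L] <= k && e >= e_lo && e <= e_hi) ++count;
    }
    return count;
}

static void check_params(const std::string& probe, int k) {
    int L = (int)probe.size();
    if (L < 1 || L > 64)
        stop("probe length must be in [1, 64] for the bitap matcher (got %d)", L);
    if (k < 0 || k >= L)
        stop("k must satisfy 0 <= k < probe length (k=%d, L=%d)", k, L);
}

// [[Rcpp::export]]
int cpp_bitap_count(std::string probe, std::string read, int k, bool edit,
                    int split, int min_flank, bool rev_comp) {
    check_params(probe, k);
    ProbeMasks pm(probe);
    int total = edit ? bitap_edit(pm, read, k, split, min_flank)
                     : bitap_hamming(pm, read, k, split, min_flank);
    if (rev_comp) {
        std::string rc = revcomp(probe);
        ProbeMasks pmr(rc);
        int L = pm.L;
        int split_rc = L - split; // split point mirrors under reverse complement
        total += edit ? bitap_edit(pmr, read, k, split_rc, min_flank)
                      : bitap_hamming(pmr, read, k, split_rc, min_flank);
    }
    return total;
}

// [[Rcpp::export]]
int cpp_naive_count(std::string probe, std::string read, int k, bool edit,
                    int split, int min_flank, bool rev_comp) {
    if (k < 0 || k >= (int)probe.size())
        stop("k must satisfy 0 <= k < probe length");
    int total = edit ? naive_edit(probe, read, k, split, min_flank)
                     : naive_hamming(probe, read, k, split, min_flank);
    if (rev_comp) {
        std::string rc = revcomp(probe);
        int split_rc = (int)probe.size() - split;
        total += edit ? naive_edit(rc, read, k, split_rc, min_flank)
                      : naive_hamming(rc, read, k, split_rc, min_flank);
    }
    return total;
}

// Occurrence counts (summed over orientations when rev_comp) for every
// (read, probe) pair. Rows = reads, columns = probes.
// [[Rcpp::export]]
IntegerMatrix cpp_hit_matrix(CharacterVector probes, IntegerVector splits,
                             CharacterVector reads, int k, bool edit,
                             int min_flank, bool rev_comp) {
    const int np = probes.size(), nr = reads.size();
    std::vector<ProbeMasks> fwd, rev;
    std::vector<int> spl(np), spl_rc(np);
    fwd.reserve(np); rev.reserve(np);
    for (int j = 0; j < np; ++j) {
        std::string p = as<std::string>(probes[j]);
        check_params(p, k);
        fwd.emplace_back(p);
        spl[j] = splits[j];
        if (rev_comp) {
            rev.emplace_back(revcomp(p));
            spl_rc[j] = (int)p.size() - splits[j];
        }
    }
    IntegerMatrix out(nr, np);
    for (int i = 0; i < nr; ++i) {
        std::string rd = as<std::string>(reads[i]);
        for (int j = 0; j < np; ++j) {
            int c = edit ? bitap_edit(fwd[j], rd, k, spl[j], min_flank)
                         : bitap_hamming(fwd[j], rd, k, spl[j], min_flank);
            if (rev_comp)
                c += edit ? bitap_edit(rev[j], rd, k, spl_rc[j], min_flank)
                          : bitap_hamming(rev[j], rd, k, spl_rc[j], min_flank);
            out(i, j) = c;
        }
    }
    return out;
}

// Number of reads with at least one qualifying occurrence, per probe
// (early-exit per read; used for bulk counting).
// [[Rcpp::export]]
IntegerVector cpp_reads_with_hit(CharacterVector probes, IntegerVector splits,
                                 CharacterVector reads, int k, bool edit,
                                 int min_flank, bool rev_comp) {
    const int np = probes.size(), nr = reads.size();
    std::vector<ProbeMasks> fwd, rev;
    std::vector<int> spl(np), spl_rc(np);
    for (int j = 0; j < np; ++j) {
        std::string p = as<std::string>(probes[j]);
        check_params(p, k);
        fwd.emplace_back(p);
        spl[j] = splits[j];
        if (rev_comp) {
            rev.emplace_back(revcomp(p));
            spl_rc[j] = (int)p.size() - splits[j];
        }
    }
    IntegerVector out(np);
    for (int i = 0; i < nr; ++i) {
        std::string rd = as<std::string>(reads[i]);
        for (int j = 0; j < np; ++j) {
            int c = edit ? bitap_edit(fwd[j], rd, k, spl[j], min_flank)
                         : bitap_hamming(fwd[j], rd, k, spl[j], min_flank);
            if (c == 0 && rev_comp)
                c = edit ? bitap_edit(rev[j], rd, k, spl_rc[j], min_flank)
                         : bitap_hamming(rev[j], rd, k, spl_rc[j], min_flank);
            if (c > 0) out[j] += 1;
        }
    }
    return out;
}
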