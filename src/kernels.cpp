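#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline int baseCode(char b) {
    switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    }
    return -1;
}

static inline char compBase(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    }
    return 'N';
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::string buf;
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        size_t L = std::strlen(s);
        buf.assign(L, 'N');
        for (size_t j = 0; j < L; ++j) buf[L - 1 - j] = compBase(s[j]);
        out[i] = buf;
    }
    return out;
}

// Position-dependent deamination rate for a single-stranded library:
// terminal 5' excess decaying into an interior plateau, with suppression
// approaching the 3' terminus.  Applied before any orientation handling,
// i.e. in molecule (sequencing) orientation.
static inline double damage_rate(int i, int L, double a5, double l5,
                                 double cc, double b3, double mu3) {
    double d = (a5 * std::exp(-l5 * (i - 1)) + cc) *
               (1.0 - b3 * std::exp(-mu3 * (double)(L - i)));
    if (d < 0.0) d = 0.0;
    if (d > 1.0) d = 1.0;
    return d;
}

// Degrade molecules: C->T deamination at rate d(i, L), then a flat
// per-base sequencing error that flips to a uniformly chosen other base.
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_degrade(CharacterVector mols, double a5, double l5, double cc,
                 double b3, double mu3, double eps) {
    R_xlen_t n = mols.size();
    CharacterVector out(n);
    IntegerVector events(n);
    const char *bases = "ACGT";
    std::string buf;
    for (R_xlen_t r = 0; r < n; ++r) {
        const char *s = CHAR(STRING_ELT(mols, r));
        int L = (int)std::strlen(s);
        buf.assign(s, L);
        int ev = 0;
        for (int i = 0; i < L; ++i) {
            char b = buf[i];
            if (baseCode(b) < 0) stop("non-ACGT base in molecule %d", (int)(r + 1));
            if (b == 'C') {
                double d = damage_rate(i + 1, L, a5, l5, cc, b3, mu3);
                if (d > 0.0 && unif_rand() < d) {
                    buf[i] = 'T';
                    ++ev;
                }
            }
            if (eps > 0.0 && unif_rand() < eps) {
                int cur = baseCode(buf[i]);
                int k = (int)(unif_rand() * 3.0);
                if (k > 2) k = 2;
                // pick uniformly among the three other bases
                int nb = (cur + 1 + k) % 4;
                buf[i] = bases[nb];
            }
        }
        out[r] = buf;
        events[r] = ev;
    }
    return List::create(_["reads"] = out, _["events"] = events);
}

struct RefIndex {
    std::vector<std::vector<int8_t>> codes;
    std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t>>> kmers;
    int k;
};

static void build_index(const CharacterVector &refs, int k, RefIndex &idx) {
    int nref = refs.size();
    idx.codes.resize(nref);
    idx.k = k;
    for (int c = 0; c < nref; ++c) {
        const char *s = CHAR(STRING_ELT(refs, c));
        size_t L = std::strlen(s);
        std::vector<int8_t> &v = idx.codes[c];
        v.resize(L);
        for (size_t j = 0; j < L; ++j) v[j] = (int8_t)baseCode(s[j]);
        if ((int)L < k) continue;
        uint32_t key = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
        int run = 0; // valid bases in current window
        for (size_t j = 0; j < L; ++j) {
            int b = v[j];
            if (b < 0) { run = 0; key = 0; continue; }
            key = ((key << 2) | (uint32_t)b) & mask;
            if (++run >= k)
                idx.kmers[key].push_back({c, (int32_t)(j - k + 1)});
        }
    }
}

// Ungapped seed-and-extend toy mapper.  All exact k-mer seeds of the read
// (both strands) are looked up; each implied placement is scored by full
// ungapped mismatch count; placements with more than ceil(maxmm * L)
// mismatches are discarded.  A unique best placement gets MAPQ 37;
// tied best placements get MAPQ 0; no placement leaves the read unmapped.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int k,
                   double maxmm) {
    if (refs.size() == 0) stop("empty reference");
    RefIndex idx;
    build_index(refs, k, idx);

    R_xlen_t n = reads.size();
    IntegerVector chrom(n, NA_INTEGER), start(n, NA_INTEGER),
        nm(n, NA_INTEGER), mapq(n, NA_INTEGER);
    LogicalVector mapped(n, false), minus(n, NA_LOGICAL);

    std::vector<int8_t> fwd, rev;
    std::vector<int64_t> seen; // candidate keys for current read

    for (R_xlen_t r = 0; r < n; ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        int L = (int)std::strlen(s);
        if (L < k) continue;
        fwd.resize(L);
        rev.resize(L);
        bool ok = true;
        for (int j = 0; j < L; ++j) {
            int b = baseCode(s[j]);
            if (b < 0) { ok = false; break; }
            fwd[j] = (int8_t)b;
            rev[L - 1 - j] = (int8_t)(3 - b);
        }
        if (!ok) continue;
        int allowed = (int)std::ceil(maxmm * L);
        int bestmm = allowed + 1, nbest = 0;
        int bchrom = -1, bstart = -1, bstrand = 0;
        seen.clear();
        for (int strand = 0; strand < 2; ++strand) {
            const std::vector<int8_t> &q = strand == 0 ? fwd : rev;
            uint32_t key = 0,
                     mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
            for (int j = 0; j < L; ++j) {
                key = ((key << 2) | (uint32_t)q[j]) & mask;
                if (j < k - 1) continue;
                int sstart = j - k + 1;
                auto it = idx.kmers.find(key);
                if (it == idx.kmers.end()) continue;
                for (const auto &hit : it->second) {
                    int c = hit.first;
                    int p = hit.second - sstart;
                    if (p < 0 || p + L > (int)idx.codes[c].size()) continue;
                    int64_t ck = ((int64_t)strand << 62) |
                                 ((int64_t)c << 40) | (int64_t)p;
                    bool dup = false;
                    for (int64_t sk : seen)
                        if (sk == ck) { dup = true; break; }
                    if (dup) continue;
                    seen.push_back(ck);
                    const std::vector<int8_t> &rc = idx.codes[c];
                    int mm = 0;
                    for (int x = 0; x < L; ++x) {
                        if (rc[p + x] != q[x] && ++mm > allowed) break;
                    }
                    if (mm > allowed) continue;
                    if (mm < bestmm) {
                        bestmm = mm; nbest = 1;
                        bchrom = c; bstart = p; bstrand = strand;
                    } else if (mm == bestmm) {
                        ++nbest;
                    }
                }
            }
        }
        if (nbest > 0) {
            mapped[r] = true;
            chrom[r] = bchrom + 1;
            start[r] = bstart;
            minus[r] = (bstrand == 1);
            nm[r] = bestmm;
            mapq[r] = (nbest == 1) ? 37 : 0;
        }
    }
    return List::create(_["mapped"] = mapped, _["chrom"] = chrom,
                        _["start"] = start, _["minus"] = minus,
                        _["nm"] = nm, _["mapq"] = mapq);
}

// Tally reference-C / C->T and reference-G / G->A opportunities and
// observations per position from the 5' and 3' ends of each read, given
// reference slices already oriented to read direction.
// [[Rcpp::export]]
List cpp_substitution_profile(CharacterVector readSeqs,
                              CharacterVector refSlices, int P) {
    R_xlen_t n = readSeqs.size();
    if (refSlices.size() != n) stop("reads and reference slices differ in length");
    IntegerVector c5opp(P), c5ct(P), c3opp(P), c3ct(P);
    IntegerVector g5opp(P), g5ga(P), g3opp(P), g3ga(P);
    long long mism = 0;
    for (R_xlen_t r = 0; r < n; ++r) {
        const char *rd = CHAR(STRING_ELT(readSeqs, r));
        const char *rf = CHAR(STRING_ELT(refSlices, r));
        int L = (int)std::strlen(rd);
        if ((int)std::strlen(rf) != L)
            stop("read/reference length mismatch at read %d", (int)(r + 1));
        for (int i = 0; i < L; ++i) {
            char a = rf[i], b = rd[i];
            if (a != b && a != 'N' && b != 'N') ++mism;
            int p5 = i;          // 0-based from 5'
            int p3 = L - 1 - i;  // 0-based from 3'
            if (a == 'C') {
                if (p5 < P) { ++c5opp[p5]; if (b == 'T') ++c5ct[p5]; }
                if (p3 < P) { ++c3opp[p3]; if (b == 'T') ++c3ct[p3]; }
            } else if (a == 'G') {
                if (p5 < P) { ++g5opp[p5]; if (b == 'A') ++g5ga[p5]; }
                if (p3 < P) { ++g3opp[p3]; if (b == 'A') ++g3ga[p3]; }
            }
        }
    }
    return List::create(
        _["c5opp"] = c5opp, _["c5ct"] = c5ct, _["c3opp"] = c3opp,
        _["c3ct"] = c3ct, _["g5opp"] = g5opp, _["g5ga"] = g5ga,
        _["g3opp"] = g3opp, _["g3ga"] = g3ga,
        _["mismatches"] = (double)mism, _["nReads"] = (double)n);
}

// Probability that a read with per-position mismatch probabilities q
// passes the mapper's acceptance rule at its true locus: at most
// `allowed` mismatches in total AND at least one clean (mismatch-free)
// run of k consecutive bases (an exact seed). Transfer-matrix DP over
// positions with state (clean-run length capped at k, mismatches so
// far); used to condition contamination likelihoods on mapping success.
// `q` holds all reads' probabilities concatenated; `off` gives 0-based
// read start offsets (length nReads + 1).
// [[Rcpp::export]]
NumericVector cpp_pass_prob(NumericVector q, IntegerVector off,
                            IntegerVector allowed, int k) {
    int n = off.size() - 1;
    NumericVector out(n);
    std::vector<double> cur, nxt;
    for (int r = 0; r < n; ++r) {
        int L = off[r + 1] - off[r];
        int A = allowed[r];
        if (A < 0) A = 0;
        if (L < k) { out[r] = 0.0; continue; }
        // state index: run (0..k-1) * (A+1) + mm ; plus absorbing "found"
        // per mm count (once a seed is found only the mm ceiling matters)
        int nrun = k, nmm = A + 1;
        int S = nrun * nmm;
        cur.assign(S + nmm, 0.0);
        nxt.assign(S + nmm, 0.0);
        cur[0] = 1.0; // run 0, mm 0, not found
        for (int i = 0; i < L; ++i) {
            double qi = q[off[r] + i];
            std::fill(nxt.begin(), nxt.end(), 0.0);
            for (int run = 0; run < nrun; ++run) {
                for (int mm = 0; mm < nmm; ++mm) {
                    double p = cur[run * nmm + mm];
                    if (p == 0.0) continue;
                    // match
                    if (run + 1 >= k) nxt[S + mm] += p * (1.0 - qi);
                    else nxt[(run + 1) * nmm + mm] += p * (1.0 - qi);
                    // mismatch (dies if mm would exceed allowed)
                    if (mm + 1 < nmm) nxt[0 * nmm + (mm + 1)] += p * qi;
                }
            }
            for (int mm = 0; mm < nmm; ++mm) {
                double p = cur[S + mm];
                if (p == 0.0) continue;
                nxt[S + mm] += p * (1.0 - qi);
                if (mm + 1 < nmm) nxt[S + mm + 1] += p * qi;
            }
            std::swap(cur, nxt);
        }
        double tot = 0.0;
        for (int mm = 0; mm < nmm; ++mm) tot += cur[S + mm];
        out[r] = tot;
    }
    return out;
}
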