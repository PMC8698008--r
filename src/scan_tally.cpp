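#include <Rcpp.h>
#include <unordered_map>
#include <array>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Sliding-window haplotype tally over one chromosome of a phased allele
// matrix (two rows per animal, alleles coded 0/1/NA). For every window of W
// consecutive markers and every haplotype passing the frequency and
// expected-homozygote eligibility thresholds, emits the allele count, the
// number of animals homozygous for it, and the number of animals with a
// complete (no-missing) diplotype in the window. Haplotype keys are packed
// into 64-bit integers, so W must be <= 64; the R caller falls back to a
// string-based tally for wider windows.
//
// [[Rcpp::export]]
List scan_tally_cpp(IntegerMatrix alleles, int W, double q_min, double e_min) {
    const int R = alleles.nrow();
    const int M = alleles.ncol();
    if (R % 2 != 0) stop("allele matrix must have an even number of rows");
    if (W < 1) stop("window size must be positive");
    if (W > 64) stop("scan_tally_cpp handles window sizes up to 64 markers");
    const int n_anim = R / 2;

    std::vector<int> win_out;
    std::vector<std::string> hap_out;
    std::vector<int> cnt_out, hom_out, ncomp_out;

    if (W <= M && n_anim > 0) {
        const int S = M - W + 1;
        const uint64_t mask =
            (W == 64) ? ~uint64_t(0) : ((uint64_t(1) << W) - 1);
        std::vector<uint64_t> code(R, 0);
        std::vector<int> miss(R, 0);
        for (int r = 0; r < R; ++r) {
            uint64_t c = 0;
            int m = 0;
            for (int j = 0; j < W; ++j) {
                int a = alleles(r, j);
                if (a == NA_INTEGER) { ++m; c <<= 1; }
                else c = (c << 1) | uint64_t(a != 0);
            }
            code[r] = c & mask;
            miss[r] = m;
        }
        std::unordered_map<uint64_t, std::array<int, 2> > tab;
        tab.reserve(512);
        std::string buf(W, '0');
        for (int s = 0; s < S; ++s) {
            if (s > 0) {
                const int drop = s - 1, add = s + W - 1;
                for (int r = 0; r < R; ++r) {
                    if (alleles(r, drop) == NA_INTEGER) --miss[r];
                    int a = alleles(r, add);
                    uint64_t bit;
                    if (a == NA_INTEGER) { ++miss[r]; bit = 0; }
                    else bit = uint64_t(a != 0);
                    code[r] = ((code[r] << 1) | bit) & mask;
                }
            }
            tab.clear();
            int n_complete = 0;
            for (int a = 0; a < n_anim; ++a) {
                const int r1 = 2 * a, r2 = r1 + 1;
                if (miss[r1] || miss[r2]) continue;
                ++n_complete;
                const uint64_t c1 = code[r1], c2 = code[r2];
                std::array<int, 2>& e1 = tab[c1];
                ++e1[0];
                if (c1 == c2) {
                    ++e1[0];
                    ++e1[1];
                } else {
                    ++tab[c2][0];
                }
            }
            if (!n_complete) continue;
            const double denom = 2.0 * n_complete;
            for (std::unordered_map<uint64_t,
                     std::array<int, 2> >::const_iterator it = tab.begin();
                 it != tab.end(); ++it) {
                const double q = it->second[0] / denom;
                const double E = n_complete * q * q;
                if (q < q_min || E < e_min) continue;
                for (int j = 0; j < W; ++j)
                    buf[j] = ((it->first >> (W - 1 - j)) & 1) ? '1' : '0';
                win_out.push_back(s + 1);
                hap_out.push_back(buf);
                cnt_out.push_back(it->second[0]);
                hom_out.push_back(it->second[1]);
                ncomp_out.push_back(n_complete);
            }
        }
    }

    return List::create(_["window"] = wrap(win_out),
                        _["hap"] = wrap(hap_out),
                        _["count"] = wrap(cnt_out),
                        _["hom"] = wrap(hom_out),
                        _["n_complete"] = wrap(ncomp_out));
}

// Dosage of a focal haplotype for each animal over a marker window:
// number of the animal's two phased haplotypes identical to `focal`
// (0/1 vector of length W). Animals with any missing allele in the
// window get NA.
//
// [[Rcpp::export]]
IntegerVector window_dosage_cpp(IntegerMatrix alleles, IntegerVector focal) {
    const int R = alleles.nrow();
    const int W = focal.size();
    if (R % 2 != 0) stop("allele matrix must have an even number of rows");
    if (alleles.ncol() != W) stop("window width mismatch");
    const int n_anim = R / 2;
    IntegerVector out(n_anim);
    for (int a = 0; a < n_anim; ++a) {
        int d = 0;
        bool missing = false;
        for (int h = 0; h < 2 && !missing; ++h) {
            const int r = 2 * a + h;
            bool match = true;
            for (int j = 0; j < W; ++j) {
                const int v = alleles(r, j);
                if (v == NA_INTEGER) { missing = true; break; }
                if (v != focal[j]) match = false;
            }
            if (!missing && match) ++d;
        }
        out[a] = missing ? NA_INTEGER : d;
    }
    return out;
}
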