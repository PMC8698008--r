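#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// One meiosis per output gamete under the Haldane model: crossover count is
// Poisson with mean equal to the chromosome's genetic length in Morgans and
// crossover positions are uniform, i.e. no interference. `row_a` / `row_b`
// are 0-based row indices of the transmitting parent's two haplotypes in
// `alleles`; `morgans` gives each marker's genetic-map position. Uses R's
// RNG, so results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(IntegerMatrix alleles, IntegerVector row_a,
                               IntegerVector row_b, NumericVector morgans) {
    const int G = row_a.size();
    const int M = alleles.ncol();
    if (row_b.size() != G) stop("row index vectors differ in length");
    if (morgans.size() != M) stop("genetic map length mismatch");
    IntegerMatrix out(G, M);
    const double lo = M ? morgans[0] : 0.0;
    const double L = M ? morgans[M - 1] - lo : 0.0;
    std::vector<double> bp;
    for (int g = 0; g < G; ++g) {
        bool cur = unif_rand() < 0.5;
        const int k = (L > 0) ? int(R::rpois(L)) : 0;
        if (k == 0) {
            const int r = cur ? row_a[g] : row_b[g];
            for (int j = 0; j < M; ++j) out(g, j) = alleles(r, j);
            continue;
        }
        bp.resize(k);
        for (int i = 0; i < k; ++i) bp[i] = lo + unif_rand() * L;
        std::sort(bp.begin(), bp.end());
        int bi = 0;
        for (int j = 0; j < M; ++j) {
            while (bi < k && bp[bi] < morgans[j]) { cur = !cur; ++bi; }
            out(g, j) = alleles(cur ? row_a[g] : row_b[g], j);
        }
    }
    return out;
}
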