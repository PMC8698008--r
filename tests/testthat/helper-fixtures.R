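# Shared fixture builders. All data are generated in code; no files ship
# with the tests.

# hap_matrix from per-haplotype allele strings ("0"/"1", "N" = missing),
# two consecutive strings per animal.
hap_from_strings <- function(strings, ids = NULL, phased = TRUE) {
    rows <- lapply(strings, function(s) {
        v <- strsplit(s, "")[[1]]
        out <- suppressWarnings(as.integer(v))
        out
    })
    al <- do.call(rbind, rows)
    if (is.null(ids)) ids <- sprintf("X%02d", seq_len(nrow(al) / 2))
    hap_matrix(ids, al, phased = phased)
}

tiny_map <- function(m, chrom = "1", spacing = 1000) {
    marker_map(sprintf("%sM%03d", chrom, seq_len(m)), chrom,
               spacing * seq_len(m))
}

# Demo-scale world: small closed population with one strongly detectable,
# fully penetrant lethal haplotype (span = scan window width).
demo_sim_config <- function(seed, carrier = 0.34, penetrance = 1,
                            span = 50L) {
    sim_config(n_chromosomes = 2L, markers_per_chromosome = 512L,
               chromosome_length_bp = 2.5e7, n_founders = 200L,
               n_generations = 3L, matings_per_generation = 500L,
               offspring_per_mating = 1L, founder_haplotype_pool = 24L,
               lethal_loci = list(lethal_locus(1L, 256L, span, carrier,
                                               penetrance, 1000L)),
               seed = seed)
}

# Acceptance-scale world: the spec's stated 2000-animal / ~2000-window
# regime with a lethal haplotype at allele frequency ~0.08 (carrier 0.16).
accept_sim_config <- function(seed, penetrance = 1, carrier = 0.16) {
    sim_config(lethal_loci = list(lethal_locus(1L, 512L, 100L, carrier,
                                               penetrance, 0L)),
               seed = seed)
}

run_scan_on <- function(pop, config = scan_config()) {
    cohorts <- build_cohorts(pop$pedigree, pop$haplotypes$ids)
    scan(pop$haplotypes, pop$map, cohorts, config)
}
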