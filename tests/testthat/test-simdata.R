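# Gene-drop simulator: founders, Mendelian transmission, lethality,
# sequencing panel and file export.

small_cfg <- function(seed, ...) {
    sim_config(n_chromosomes = 1L, markers_per_chromosome = 120L,
               chromosome_length_bp = 6e6, n_founders = 40L,
               n_generations = 2L, matings_per_generation = 60L,
               offspring_per_mating = 1L, founder_haplotype_pool = 10L,
               seed = seed, ...)
}

test_that("n_generations = 0 gives founders only, without parent links", {
    cfg <- sim_config(n_chromosomes = 1L, markers_per_chromosome = 60L,
                      chromosome_length_bp = 6e6, n_founders = 12L,
                      n_generations = 0L, trio_fraction = 1,
                      founder_haplotype_pool = 0L, seed = 3L)
    pop <- simulate_population(cfg)
    expect_equal(nrow(pop$pedigree), 12L)
    expect_true(all(pop$pedigree$sire_id == "0"))
    expect_true(all(pop$pedigree$dam_id == "0"))
    expect_equal(length(pop$haplotypes$ids), 12L)
    co <- build_cohorts(pop$pedigree, pop$haplotypes$ids)
    expect_equal(nrow(co$trios), 0L)
    expect_equal(nrow(co$pgp), 0L)
})

test_that("same config and seed give byte-identical exports", {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    cfg <- small_cfg(99, lethal_loci = list(
        lethal_locus(1L, 60L, 20L, 0.2, 1)))
    export_population(simulate_population(cfg), d1)
    export_population(simulate_population(cfg), d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)
    }
})

test_that("every transmitted haplotype is Mendelian-consistent per site", {
    pop <- simulate_population(small_cfg(5))
    al <- pop$haplotypes$alleles
    idx <- setNames(seq_along(pop$haplotypes$ids), pop$haplotypes$ids)
    ped <- pop$pedigree
    checked <- 0L
    for (k in which(ped$sire_id != "0")) {
        o <- idx[ped$animal_id[k]]; s <- idx[ped$sire_id[k]]
        d <- idx[ped$dam_id[k]]
        if (anyNA(c(o, s, d))) next
        pat <- al[2 * o - 1, ]
        mat <- al[2 * o, ]
        expect_true(all(pat == al[2 * s - 1, ] | pat == al[2 * s, ]))
        expect_true(all(mat == al[2 * d - 1, ] | mat == al[2 * d, ]))
        checked <- checked + 1L
        if (checked >= 25L) break
    }
    expect_gt(checked, 0L)
})

test_that("without lethality, homozygote fraction is ~ q^2 (binomial check)", {
    cfg <- sim_config(n_chromosomes = 1L, markers_per_chromosome = 200L,
                      chromosome_length_bp = 1e7, n_founders = 150L,
                      n_generations = 2L, matings_per_generation = 800L,
                      offspring_per_mating = 1L, founder_haplotype_pool = 20L,
                      trio_fraction = 1,
                      lethal_loci = list(lethal_locus(1L, 100L, 40L, 0.2, 0)),
                      seed = 21L)
    pop <- simulate_population(cfg)
    tr <- pop$truth
    span <- seq.int(tr$span_start_marker, tr$span_end_marker)
    hstr <- as.integer(strsplit(tr$hap, "")[[1]])
    dos <- haplodeficit:::window_dosage_cpp(
        pop$haplotypes$alleles[, span, drop = FALSE], hstr)
    n <- sum(!is.na(dos))
    qhat <- sum(dos, na.rm = TRUE) / (2 * n)
    obs_hom <- sum(dos == 2, na.rm = TRUE)
    exp_hom <- n * qhat^2
    se <- sqrt(n * qhat^2 * (1 - qhat^2))
    expect_lt(abs(obs_hom - exp_hom), 3 * se + 1)
    expect_equal(tr$n_removed, 0L)
})

test_that("apply_lethality honours penetrance exactly at the extremes", {
    cfg <- small_cfg(8, lethal_loci = list(lethal_locus(1L, 60L, 20L, 0.3, 0)),
                     trio_fraction = 1)
    pop <- simulate_population(cfg)
    hom0 <- pop$truth$n_homozygotes_genotyped
    expect_gt(hom0, 0L)  # penetrance 0: homozygotes survive to genotyping
    spec0 <- lethal_locus(1L, 60L, 20L, 0.3, 0)
    expect_equal(apply_lethality(pop, spec0)$truth$n_homozygotes_genotyped,
                 hom0)
    spec1 <- lethal_locus(1L, 60L, 20L, 0.3, 1)
    culled <- apply_lethality(pop, spec1)
    expect_equal(culled$truth$n_homozygotes_genotyped, 0L)
    expect_equal(length(culled$removed_ids), hom0)
    expect_false(any(culled$removed_ids %in% culled$haplotypes$ids))
})

test_that("partial penetrance removes ~penetrance of homozygotes (pooled)", {
    tot_hom <- 0L; tot_gone <- 0L
    for (seed in 41:45) {
        cfg <- small_cfg(seed, trio_fraction = 1, lethal_loci = list(
            lethal_locus(1L, 60L, 20L, 0.35, 0)))
        pop <- simulate_population(cfg)
        hom <- pop$truth$n_homozygotes_genotyped
        out <- apply_lethality(pop, lethal_locus(1L, 60L, 20L, 0.35, 0.9))
        tot_hom <- tot_hom + hom
        tot_gone <- tot_gone + (hom - out$truth$n_homozygotes_genotyped)
    }
    se <- sqrt(tot_hom * 0.9 * 0.1)
    expect_lt(abs(tot_gone - 0.9 * tot_hom), 3 * se + 1)
})

test_that("full penetrance during the drop leaves zero genotyped homozygotes", {
    cfg <- small_cfg(13, lethal_loci = list(lethal_locus(1L, 60L, 20L, 0.3, 1)))
    pop <- simulate_population(cfg)
    expect_equal(pop$truth$n_homozygotes_genotyped, 0L)
    expect_gt(pop$truth$n_carriers_genotyped, 0L)
    expect_false(any(pop$removed_ids %in% pop$haplotypes$ids))
    # removed animals stay in the pedigree but never as parents
    expect_true(all(pop$removed_ids %in% pop$pedigree$animal_id))
    expect_false(any(pop$removed_ids %in%
                     c(pop$pedigree$sire_id, pop$pedigree$dam_id)))
})

test_that("unreachable target carrier frequency names the locus", {
    expect_error(
        simulate_population(sim_config(
            n_chromosomes = 1L, markers_per_chromosome = 60L,
            chromosome_length_bp = 6e6, n_founders = 50L,
            n_generations = 0L, founder_haplotype_pool = 5L,
            lethal_loci = list(lethal_locus(1L, 30L, 10L, 0.005, 1)),
            seed = 1L)),
        "lethal locus 1.*unreachable")
})

test_that("sequence panel: causal variant co-segregates perfectly", {
    cfg <- small_cfg(17, lethal_loci = list(lethal_locus(1L, 60L, 20L, 0.3, 1)))
    pop <- simulate_population(cfg)
    panel0 <- attach_sequence_panel(pop, n_carriers = 3L,
                                    n_background_variants = 0L)
    expect_equal(nrow(panel0$variants), 1L)  # exactly one variant per locus
    panel <- attach_sequence_panel(pop, n_carriers = 3L,
                                   n_background_variants = 30L)
    v <- panel$variants
    ci <- which(v$causal)
    expect_length(ci, 1L)
    # dosage equals diplotype for every panel animal -> r^2 = 1
    tr <- pop$truth
    win <- list(start_idx = tr$span_start_marker,
                end_idx = tr$span_end_marker)
    dip <- diplotypes(pop$haplotypes, win, tr$hap, panel$samples)
    expect_equal(unname(panel$dosages[ci, ]), unname(dip[panel$samples]))
    expect_equal(ld_r2(dip, panel$dosages[ci, ])$r_squared, 1)
    expect_true(any(dip == 0) && any(dip == 1))  # carriers and non-carriers
    expect_error(attach_sequence_panel(pop, n_carriers = 10000L),
                 "carriers")
})

test_that("permuted background dosages have mean r^2 near 1/(n-1)", {
    cfg <- small_cfg(19, lethal_loci = list(lethal_locus(1L, 60L, 20L, 0.3, 1)))
    pop <- simulate_population(cfg)
    panel <- attach_sequence_panel(pop, n_carriers = 6L,
                                   n_background_variants = 5L,
                                   n_noncarriers = 6L)
    tr <- pop$truth
    dip <- diplotypes(pop$haplotypes,
                      list(start_idx = tr$span_start_marker,
                           end_idx = tr$span_end_marker),
                      tr$hap, panel$samples)
    bg <- panel$dosages[which(!panel$variants$causal)[1L], ]
    set.seed(1)
    r2 <- replicate(4000, {
        r <- ld_r2(dip, sample(bg))
        if (r$defined) r$r_squared else NA_real_
    })
    n <- length(dip)
    # under independence E[r^2] = 1/(n-1); allow Monte-Carlo slack
    expect_lt(abs(mean(r2, na.rm = TRUE) - 1 / (n - 1)), 0.03)
})

test_that("export round-trips losslessly through load_dataset", {
    d <- withr::local_tempdir()
    cfg <- small_cfg(23, genotype_missing_rate = 0.1,
                     lethal_loci = list(lethal_locus(1L, 60L, 20L, 0.3, 1)))
    pop <- simulate_population(cfg)
    paths <- export_population(pop, d)
    expect_true(all(file.exists(paths)))
    ds <- load_dataset(paths["vcf"], paths["pedigree"])
    expect_identical(ds$haplotypes$ids, pop$haplotypes$ids)
    expect_identical(ds$haplotypes$alleles, pop$haplotypes$alleles)
    expect_true(all(ds$haplotypes$phased))
    expect_equal(ds$map$pos_bp, pop$map$pos_bp)
    expect_identical(as.data.frame(ds$pedigree),
                     as.data.frame(pop$pedigree))
    # VCF record count = markers
    expect_equal(sum(!startsWith(readLines(paths["vcf"]), "#")),
                 nrow(pop$map))
    # loader call rates match the ./. counts written per animal
    lines <- readLines(paths["vcf"])
    body <- lines[!startsWith(lines, "#")]
    gts <- do.call(rbind, strsplit(body, "\t"))[, -(1:9), drop = FALSE]
    file_rate <- 1 - colMeans(gts == "./.")
    expect_equal(unname(animal_call_rate(ds$haplotypes)), unname(file_rate))
})
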