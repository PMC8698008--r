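# Loading, validation, QC filtering, cohorts and trio phasing.

write_tiny_vcf <- function(path, gts, ids = NULL, alt = "C") {
    # gts: matrix of GT strings, markers x samples
    if (is.null(ids)) ids <- sprintf("S%02d", seq_len(ncol(gts)))
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=1,length=100000>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
    body <- vapply(seq_len(nrow(gts)), function(i)
        paste(c("1", 1000 * i, sprintf("m%03d", i), "A", alt, ".", "PASS",
                ".", "GT", gts[i, ]), collapse = "\t"), character(1))
    writeLines(c(hdr, body), path)
    path
}

write_tiny_ped <- function(path, animal, sire, dam, sex) {
    write_pedigree_tsv(pedigree(animal, sire, dam, sex), path)
}

test_that("load_dataset round-trips a simdata export (shape 2n x M)", {
    d <- withr::local_tempdir()
    cfg <- sim_config(n_chromosomes = 1L, markers_per_chromosome = 50L,
                      chromosome_length_bp = 5e6, n_founders = 10L,
                      n_generations = 0L, founder_haplotype_pool = 0L,
                      trio_fraction = 1, seed = 2L)
    paths <- export_population(simulate_population(cfg), d)
    ds <- load_dataset(paths["vcf"], paths["pedigree"])
    expect_equal(dim(ds$haplotypes$alleles), c(20L, 50L))
    expect_equal(nrow(ds$map), 50L)
})

test_that("a single '/' genotype flags that animal unphased", {
    d <- withr::local_tempdir()
    vcf <- write_tiny_vcf(file.path(d, "t.vcf"),
                          rbind(c("0|1", "0/1", "./."),
                                c("1|1", "0|0", "1|0")))
    ped <- write_tiny_ped(file.path(d, "p.tsv"),
                          c("S01", "S02", "S03"), "0", "0", "0")
    ds <- load_dataset(vcf, ped)
    expect_identical(unname(ds$haplotypes$phased), c(TRUE, FALSE, TRUE))
    # missing genotypes are neutral for the phase flag and read as NA
    expect_true(all(is.na(ds$haplotypes$alleles[5:6, 1])))
})

test_that("multi-allelic records are rejected by name", {
    d <- withr::local_tempdir()
    vcf <- write_tiny_vcf(file.path(d, "t.vcf"),
                          rbind(c("0|1", "0|2")), alt = "C,T")
    ped <- write_tiny_ped(file.path(d, "p.tsv"), c("S01", "S02"),
                          "0", "0", "0")
    expect_error(load_dataset(vcf, ped), "multi-allelic.*m001")
})

test_that("pedigree validation catches loops and sex misuse", {
    expect_error(pedigree(c("A", "B"), c("B", "A"), c("0", "0"),
                          c("M", "M")),
                 "loop.*A")
    expect_error(pedigree(c("A", "B", "C"), c("0", "0", "A"),
                          c("0", "0", "B"), c("M", "M", "F")),
                 "male id\\(s\\) used as dam: B")
    expect_error(pedigree(c("A", "A"), "0", "0", "M"), "duplicate")
})

test_that("QC removes low call-rate animals, then SNPs, then low-MAF markers", {
    # 10 animals x 10 markers, all hets (MAF 0.5), one animal 70% called
    strings <- rep("1111111111", 20)
    strings[2] <- "1111111NNN"
    strings[seq(1, 20, 2)] <- "0000000000"
    strings[1] <- "0000000NNN"
    hm <- hap_from_strings(strings)
    map <- tiny_map(10)
    res <- qc_filter(hm, map, qc_thresholds())
    expect_equal(res$report$entity[res$report$type == "animal"], "X01")
    expect_equal(res$report$value[res$report$type == "animal"], 0.7)
    expect_false("X01" %in% res$haplotypes$ids)
    # markers survive: all remaining animals fully called, MAF 0.5
    expect_equal(nrow(res$map), 10L)

    # minor allele count 1 across 100 animals -> MAF 0.005 < 0.01
    al <- matrix(0L, nrow = 200, ncol = 2)
    al[, 2] <- rep(c(0L, 1L), 100)  # marker 2 is a clean het everywhere
    al[1, 1] <- 1L                  # marker 1 has a single minor allele
    hm2 <- hap_matrix(sprintf("A%03d", 1:100), al)
    res2 <- qc_filter(hm2, tiny_map(2), qc_thresholds())
    expect_equal(res2$report$reason, "low_maf")
    expect_equal(res2$report$value, 0.005)
    expect_equal(res2$map$marker_id, "1M002")

    # clean matrix with zero thresholds: identity
    res3 <- qc_filter(hm2, tiny_map(2),
                      qc_thresholds(min_maf = 0, min_snp_call_rate = 0,
                                    min_animal_call_rate = 0))
    expect_identical(res3$haplotypes$alleles, hm2$alleles)
    expect_equal(nrow(res3$report), 0L)
})

test_that("QC is idempotent", {
    set.seed(5)
    al <- matrix(sample(c(0L, 1L, NA), 600, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), nrow = 30)
    hm <- hap_matrix(sprintf("A%02d", 1:15), al)
    r1 <- qc_filter(hm, tiny_map(20), qc_thresholds(min_snp_call_rate = 0.8))
    r2 <- qc_filter(r1$haplotypes, r1$map,
                    qc_thresholds(min_snp_call_rate = 0.8))
    expect_identical(r2$haplotypes$alleles, r1$haplotypes$alleles)
    expect_equal(nrow(r2$report), 0L)
})

test_that("cohort construction follows the hand-enumerated 5-animal pedigree", {
    # G (mgs) -> D (dam); S (sire); O1 offspring of S x D (all genotyped)
    # O2 offspring of S x U (dam U ungenotyped, U's sire G genotyped)
    ped <- pedigree(c("G", "D", "U", "S", "O1", "O2"),
                    c("0", "G", "G", "0", "S", "S"),
                    c("0", "0", "0", "0", "D", "U"),
                    c("M", "F", "F", "M", "M", "F"))
    g <- c("G", "D", "S", "O1", "O2")
    co <- build_cohorts(ped, g)
    expect_equal(co$trios$offspring, "O1")       # O2's dam not genotyped
    expect_setequal(co$pgp$offspring, c("O1", "O2"))
    expect_equal(co$pgp$mgs, c("G", "G"))
    # order invariance
    perm <- ped[c(4, 6, 1, 3, 5, 2), ]
    co2 <- build_cohorts(perm, g)
    expect_setequal(co2$trios$offspring, co$trios$offspring)
    expect_setequal(co2$pgp$offspring, co$pgp$offspring)
    # disjoint mode removes trio offspring from pgp
    co3 <- build_cohorts(ped, g, disjoint = TRUE)
    expect_equal(co3$pgp$offspring, "O2")
})

test_that("trio phasing resolves forced sites, flags ambiguity and errors", {
    # markers: m1 forced by two homozygous parents, m2/m3 exercise the
    # Mendelian check, m4 forced by the homozygous dam only
    al <- rbind(c(0L, 1L, 1L, 0L),   # O hap1
                c(1L, 1L, 1L, 1L),   # O hap2 -> gt 0/1, 1/1, 1/1, 0/1
                c(0L, 0L, 0L, 1L),   # S hap1
                c(0L, 1L, 0L, 0L),   # S hap2 -> gt 0/0, 0/1, 0/0, 0/1
                c(1L, 0L, 1L, 1L),   # D hap1
                c(1L, 1L, 1L, 1L))   # D hap2 -> gt 1/1, 0/1, 1/1, 1/1
    hm <- hap_matrix(c("O", "S", "D"), al, phased = FALSE)
    ped <- pedigree(c("O", "S", "D"), c("S", "0", "0"), c("D", "0", "0"),
                    c("M", "M", "F"))
    out <- trio_phase(hm, ped)
    rep <- attr(out, "report")
    # m1: offspring 0/1, sire hom 0, dam hom 1 -> paternal 0, maternal 1
    expect_equal(out$alleles[1, 1], 0L)
    expect_equal(out$alleles[2, 1], 1L)
    # m4: offspring 0/1, sire het, dam hom 1 -> maternal 1, paternal 0
    expect_equal(out$alleles[1, 4], 0L)
    expect_equal(out$alleles[2, 4], 1L)
    # m3: offspring 1/1 with 0/0 sire -> Mendelian error, flagged not fatal
    expect_equal(rep$n_mendel_errors, 1L)
    # genotypes unchanged everywhere (phase only)
    gt_of <- function(m) apply(m$alleles, 2, function(col)
        paste(sort(col[1:2]), collapse = "/"))
    expect_equal(gt_of(out), gt_of(hm))
    expect_true(out$phased[1])
})

test_that("trio phasing recovers >= 99% of resolvable simulated phases", {
    cfg <- sim_config(n_chromosomes = 1L, markers_per_chromosome = 150L,
                      chromosome_length_bp = 7.5e6, n_founders = 30L,
                      n_generations = 1L, matings_per_generation = 60L,
                      offspring_per_mating = 1L, founder_haplotype_pool = 8L,
                      trio_fraction = 1, seed = 31L)
    pop <- simulate_population(cfg)
    truth <- pop$haplotypes
    # strip phase: sort each genotype's alleles so phase is destroyed
    al <- truth$alleles
    n <- length(truth$ids)
    for (a in seq_len(n)) {
        r <- 2 * a - 1
        swap <- al[r, ] > al[r + 1, ]
        tmp <- al[r, swap]
        al[r, swap] <- al[r + 1, swap]
        al[r + 1, swap] <- tmp
    }
    unph <- hap_matrix(truth$ids, al, phased = FALSE)
    out <- trio_phase(unph, pop$pedigree)
    co <- build_cohorts(pop$pedigree, truth$ids)
    good <- 0L; tot <- 0L
    for (o in co$trios$offspring) {
        i <- match(o, truth$ids)
        het <- truth$alleles[2 * i - 1, ] != truth$alleles[2 * i, ]
        resolved <- het
        if (!is.null(out$unresolved))
            resolved[out$unresolved[out$unresolved[, 1] == i, 2]] <- FALSE
        tot <- tot + sum(resolved)
        good <- good + sum(out$alleles[2 * i - 1, resolved] ==
                           truth$alleles[2 * i - 1, resolved])
    }
    expect_gt(tot, 200L)
    expect_gte(good / tot, 0.99)
})
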