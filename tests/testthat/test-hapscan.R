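# Window enumeration, haplotype tallies, diplotypes, expectations, the
# scan itself, and region building.

test_that("window counts follow M - W + 1 per chromosome", {
    cfgW <- scan_config(window_size = 50L)
    expect_equal(nrow(enumerate_windows(tiny_map(100), cfgW)), 51L)
    expect_equal(nrow(enumerate_windows(tiny_map(50), cfgW)), 1L)
    map2 <- marker_map(c(sprintf("a%02d", 1:60), sprintf("b%02d", 1:60)),
                       rep(c("1", "2"), each = 60),
                       c(1000 * (1:60), 1000 * (1:60)))
    w <- enumerate_windows(map2, cfgW)
    expect_equal(nrow(w), 22L)
    expect_equal(as.vector(table(w$chrom)), c(11L, 11L))
    expect_true(all(w$end_idx - w$start_idx + 1L == 50L))
    expect_warning(enumerate_windows(tiny_map(10), cfgW), "skipped")
})

test_that("window haplotype tallies match direct counting", {
    # 4 identical animals -> single haplotype with q = 1
    hm <- hap_from_strings(rep("01101", 8))
    wh <- window_haplotypes(hm, list(start_idx = 1, end_idx = 5))
    expect_equal(wh$table$hap, "01101")
    expect_equal(wh$table$q, 1)
    # {H1,H1} and {H1,H2} -> q(H1) = 0.75, q(H2) = 0.25
    hm2 <- hap_from_strings(c("111", "111", "111", "000"))
    wh2 <- window_haplotypes(hm2, list(start_idx = 1, end_idx = 3))
    expect_equal(wh2$table$q[wh2$table$hap == "111"], 0.75)
    expect_equal(wh2$table$q[wh2$table$hap == "000"], 0.25)
    expect_equal(sum(wh2$table$q), 1)
})

test_that("C++ tally agrees with a naive string-tally oracle (with missing)", {
    set.seed(11)
    al <- matrix(sample(c(0L, 1L, NA), 40 * 30, replace = TRUE,
                        prob = c(0.48, 0.48, 0.04)), nrow = 40)
    hm <- hap_matrix(sprintf("A%02d", 1:20), al)
    W <- 7L
    t <- haplodeficit:::scan_tally_cpp(al, W, 0, 0)
    for (s in unique(t$window)) {
        wh <- window_haplotypes(hm, list(start_idx = s, end_idx = s + W - 1L))
        sel <- t$window == s
        expect_equal(sort(t$hap[sel]), sort(wh$table$hap))
        expect_equal(t$count[sel][order(t$hap[sel])],
                     wh$table$count[order(wh$table$hap)])
        expect_equal(unique(t$n_complete[sel]), wh$n_complete)
        # homozygote counts against diplotype dosages
        for (h in t$hap[sel]) {
            d <- diplotypes(hm, list(start_idx = s, end_idx = s + W - 1L), h)
            expect_equal(t$hom[sel][t$hap[sel] == h],
                         sum(d == 2L, na.rm = TRUE))
        }
        # frequencies sum to 1 over complete haplotypes
        expect_equal(sum(wh$table$q), 1)
    }
})

test_that("diplotype dosages and the 2nq identity", {
    hm <- hap_from_strings(c("11", "11", "11", "00", "01", "10"))
    win <- list(start_idx = 1, end_idx = 2)
    d <- diplotypes(hm, win, "11")
    expect_equal(unname(d), c(2L, 1L, 0L))
    wh <- window_haplotypes(hm, win)
    for (h in wh$table$hap) {
        dd <- diplotypes(hm, win, h)
        q <- wh$table$q[wh$table$hap == h]
        expect_equal(sum(dd), 2 * wh$n_complete * q)
    }
})

test_that("expected homozygotes: HWE and transmission modes", {
    expect_equal(expected_homozygotes(9965, 0.062), 38.3, tolerance = 1e-3)
    # one pgp offspring, sire het, mgs het, q = 0 -> 1/8
    expect_equal(expected_homozygotes(
        NA, 0, mode = "transmission",
        pgp_dosages = data.frame(d_sire = 1, d_mgs = 1)), 1 / 8)
    # one trio offspring, both parents het -> 1/4
    expect_equal(expected_homozygotes(
        NA, 0.5, mode = "transmission",
        trio_dosages = data.frame(d_sire = 1, d_dam = 1)), 1 / 4)
    expect_error(expected_homozygotes(10, 1.2), "q must")
})

test_that("scan finds the lethal haplotype as its top record with O = 0", {
    skip_if_not_installed("withr")
    for (seed in c(3L, 14L)) {
        pop <- simulate_population(demo_sim_config(seed))
        rec <- run_scan_on(pop)
        expect_gt(nrow(rec), 1000)
        top <- rec[order(rec$p, -rec$deficiency), ][1L, ]
        tr <- pop$truth
        expect_equal(top$chrom, tr$chrom)
        expect_lte(top$start_idx, tr$span_end_marker)
        expect_gte(top$end_idx, tr$span_start_marker)
        expect_equal(top$observed, 0L)
        expect_equal(top$deficiency, 100)
        # zero-observed deficiency is exactly 100 across all records
        expect_true(all(rec$deficiency[rec$observed == 0] == 100))
        # the diplotype-sum identity holds for the top record
        d <- diplotypes(pop$haplotypes,
                        list(start_idx = top$start_idx,
                             end_idx = top$end_idx), top$hap)
        offs <- unique(build_cohorts(pop$pedigree,
                                     pop$haplotypes$ids)$trios$offspring)
        if (top$approach == "pgp")
            offs <- unique(build_cohorts(pop$pedigree,
                                         pop$haplotypes$ids)$pgp$offspring)
        expect_equal(sum(d[offs], na.rm = TRUE), 2 * top$n * top$q)
    }
})

test_that("BY family is per cohort run and significance respects alpha", {
    pop <- simulate_population(demo_sim_config(3L))
    co <- build_cohorts(pop$pedigree, pop$haplotypes$ids)
    both <- scan(pop$haplotypes, pop$map, co, scan_config(cohort_mode = "both"))
    trio <- scan(pop$haplotypes, pop$map, co, scan_config(cohort_mode = "trio"))
    bt <- both[both$approach == "trio", ]
    rownames(bt) <- NULL
    expect_equal(bt$p_adj, trio$p_adj)
    expect_identical(both$significant, both$p_adj < 0.05)
})

test_that("regions merge overlapping windows and label shared regions", {
    map <- tiny_map(100)
    base <- data.frame(chrom = "1", n = 100L, q = 0.1, observed = 0L,
                       expected = 5, deficiency = 100, p = 1e-6,
                       p_adj = 1e-4, significant = TRUE,
                       hap = "h", stringsAsFactors = FALSE)
    rec <- rbind(cbind(approach = "trio", start_idx = 10L, end_idx = 59L,
                       start_bp = 10000, end_bp = 59000, base),
                 cbind(approach = "trio", start_idx = 11L, end_idx = 60L,
                       start_bp = 11000, end_bp = 60000, base))
    reg <- build_regions(rec, map, scan_config())
    expect_equal(nrow(reg), 1L)
    expect_equal(reg$start_idx, 10L)
    expect_equal(reg$end_idx, 60L)
    expect_equal(reg$ext_start_bp, 1)                # clipped at chrom start
    expect_equal(reg$ext_end_bp, 100000)             # clipped at chrom end
    # two chromosomes -> two regions
    map2 <- marker_map(c(sprintf("a%02d", 1:60), sprintf("b%02d", 1:60)),
                       rep(c("1", "2"), each = 60),
                       c(1000 * (1:60), 1000 * (1:60)))
    rec2 <- rbind(cbind(approach = "trio", start_idx = 1L, end_idx = 50L,
                        start_bp = 1000, end_bp = 50000, base),
                  cbind(approach = "trio", start_idx = 61L, end_idx = 110L,
                        start_bp = 1000, end_bp = 50000, base))
    rec2$chrom <- c("1", "2")
    reg2 <- build_regions(rec2, map2, scan_config())
    expect_equal(length(unique(reg2$region_id)), 2L)
    # no significant records -> empty frame, not an error
    rec3 <- rec
    rec3$significant <- FALSE
    expect_equal(nrow(build_regions(rec3, map, scan_config())), 0L)
})

test_that("7 trio + 9 pgp regions with 5 shared merge to a union of 11", {
    mk <- function(approach, k, chrom, start) {
        data.frame(approach = approach, chrom = as.character(chrom),
                   start_bp = start, end_bp = start + 5e5,
                   stringsAsFactors = FALSE)
    }
    # 5 shared positions, 2 trio-only, 4 pgp-only
    shared <- lapply(1:5, function(i) rbind(mk("trio", i, i, 1e6),
                                            mk("pgp", i, i, 1.2e6)))
    trio_only <- lapply(1:2, function(i) mk("trio", i, 10 + i, 1e6))
    pgp_only <- lapply(1:4, function(i) mk("pgp", i, 20 + i, 1e6))
    all <- do.call(rbind, c(shared, trio_only, pgp_only))
    merged <- merge_region_sets(all)
    expect_equal(sum(merged$approach == "trio"), 7L)
    expect_equal(sum(merged$approach == "pgp"), 9L)
    expect_equal(length(unique(merged$region_id)), 11L)
    expect_equal(sum(merged$approaches == "trio and pgp"), 10L)  # 5 x 2 rows
})

test_that("transmission expectation mode runs and matches hand numbers", {
    # family: sire het, dam het, offspring heterozygous carrier
    al <- rbind(c(1L, 1L), c(0L, 0L),   # S: one copy of "11"
                c(1L, 1L), c(0L, 0L),   # D: one copy
                c(1L, 1L), c(0L, 0L))   # O: one copy, not homozygous
    hm <- hap_matrix(c("S", "D", "O"), al)
    ped <- pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"),
                    c("M", "F", "M"))
    co <- build_cohorts(ped, c("S", "D", "O"))
    cfg <- scan_config(window_size = 2L, expected_mode = "transmission",
                       cohort_mode = "trio",
                       min_haplotype_freq = 0, min_expected_homozygotes = 0)
    rec <- scan(hm, tiny_map(2), co, cfg)
    r11 <- rec[rec$hap == "11", ]
    expect_equal(r11$expected, 0.25)        # (1/2)(1/2)
    expect_equal(r11$observed, 0L)
    expect_equal(r11$p, 0.75)               # P(no homozygote | p=1/4)
})
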