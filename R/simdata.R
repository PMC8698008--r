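#' Specification of one embedded recessive-lethal haplotype
#'
#' Describes a founder haplotype segment that is tracked identically by
#' descent and whose homozygotes are removed before genotyping with
#' probability `penetrance` (1 = fully penetrant embryonic lethal, as for
#' a complete deficit of homozygotes; values below 1 give the partial
#' deficits seen for incompletely penetrant alleles).
#'
#' @param chromosome chromosome index (1-based).
#' @param center_marker marker index (within the chromosome) at the centre
#'   of the tracked segment.
#' @param span_markers number of consecutive markers made identical across
#'   carrier founders; the tracked unit is this multi-marker haplotype.
#' @param target_carrier_frequency intended fraction of heterozygous
#'   carriers among founders, in (0, 0.5); the haplotype (allele) frequency
#'   is half of this.
#' @param penetrance probability that a homozygote is removed before
#'   genotyping, in `[0, 1]`.
#' @param linked_variant_offset_bp distance (bp) of the perfectly linked
#'   causal variant from the segment's centre marker.
#' @return A `lethal_locus` list.
#' @export
lethal_locus <- function(chromosome = 1L, center_marker = 500L,
                         span_markers = 100L,
                         target_carrier_frequency = 0.16,
                         penetrance = 1, linked_variant_offset_bp = 0L) {
    stopifnot(.is_count(chromosome, 1L), .is_count(center_marker, 1L),
              .is_count(span_markers, 2L))
    if (!.is_prob(target_carrier_frequency) ||
        target_carrier_frequency <= 0 || target_carrier_frequency >= 0.5)
        .stopf("target_carrier_frequency must lie in (0, 0.5)")
    if (!.is_prob(penetrance)) .stopf("penetrance must lie in [0, 1]")
    structure(list(chromosome = as.integer(chromosome),
                   center_marker = as.integer(center_marker),
                   span_markers = as.integer(span_markers),
                   target_carrier_frequency = target_carrier_frequency,
                   penetrance = penetrance,
                   linked_variant_offset_bp =
                       as.integer(linked_variant_offset_bp)),
              class = "lethal_locus")
}

#' Configuration for the gene-drop population simulator
#'
#' Defaults describe the package's reduced-scale stand-in for a closed,
#' routinely genotyped dual-purpose cattle population: ~2 x 1025 markers on
#' two 50-Mb chromosomes (about 1 marker per 50 kb), 100 founders expanded
#' by four generations of random union of gametes to 2000 animals, and a
#' founder haplotype pool of limited size so that window haplotypes
#' segregate at the few-percent frequencies typical of a closed breed.
#'
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp genome
#'   layout; markers are evenly spaced.
#' @param n_founders number of founder animals (sexes alternate M/F).
#' @param n_generations generations of gene drop after the founders.
#' @param matings_per_generation,offspring_per_mating matings are random
#'   union of gametes with parents drawn (with replacement) from all
#'   surviving animals of earlier cohorts.
#' @param founder_minor_allele_freq_range interval in (0, 0.5] from which
#'   each marker's founder minor-allele frequency is drawn.
#' @param founder_haplotype_pool number of distinct haplotypes per
#'   chromosome from which founder chromosomes are sampled; `0` draws
#'   every founder chromosome independently marker by marker.
#' @param lethal_loci list of [lethal_locus()] specifications.
#' @param genotype_missing_rate per-genotype probability of a missing call.
#' @param genotype_error_rate per-genotype probability that one allele is
#'   flipped after phasing (imputation/array noise stand-in).
#' @param trio_fraction probability that a female is genotyped (males are
#'   always genotyped); drives the trio vs parent-grandparent cohort split.
#' @param recomb_cm_per_mb constant recombination rate (Haldane model);
#'   1 cM/Mb, i.e. 1 Morgan per 100 Mb, unless configured otherwise.
#' @param seed integer RNG seed; the whole simulation is reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, markers_per_chromosome = 1025L,
                       chromosome_length_bp = 5e7, n_founders = 100L,
                       n_generations = 4L, matings_per_generation = 475L,
                       offspring_per_mating = 1L,
                       founder_minor_allele_freq_range = c(0.05, 0.5),
                       founder_haplotype_pool = 30L,
                       lethal_loci = list(),
                       genotype_missing_rate = 0,
                       genotype_error_rate = 0,
                       trio_fraction = 0.85,
                       recomb_cm_per_mb = 1,
                       seed = 1L) {
    stopifnot(.is_count(n_chromosomes, 1L),
              .is_count(markers_per_chromosome, 2L),
              .is_count(n_founders, 2L),
              .is_count(n_generations, 0L),
              .is_count(matings_per_generation, 1L),
              .is_count(offspring_per_mating, 1L),
              .is_count(founder_haplotype_pool, 0L),
              length(chromosome_length_bp) == 1L,
              chromosome_length_bp >= markers_per_chromosome,
              length(seed) == 1L, is.finite(seed))
    rng <- founder_minor_allele_freq_range
    if (length(rng) != 2L || rng[1] <= 0 || rng[2] > 0.5 || rng[1] > rng[2])
        .stopf("founder_minor_allele_freq_range must lie within (0, 0.5]")
    for (p in c(genotype_missing_rate, genotype_error_rate, trio_fraction))
        if (!.is_prob(p)) .stopf("rates and fractions must lie in [0, 1]")
    if (recomb_cm_per_mb < 0) .stopf("recomb_cm_per_mb must be >= 0")
    for (i in seq_along(lethal_loci)) {
        ll <- lethal_loci[[i]]
        if (!inherits(ll, "lethal_locus"))
            .stopf("lethal_loci[[%d]] is not a lethal_locus()", i)
        if (ll$chromosome > n_chromosomes)
            .stopf("lethal locus %d lies on chromosome %d of %d", i,
                   ll$chromosome, n_chromosomes)
        s <- ll$center_marker - ll$span_markers %/% 2L
        if (s < 1L || s + ll$span_markers - 1L > markers_per_chromosome)
            .stopf("lethal locus %d span exceeds its chromosome", i)
    }
    structure(list(n_chromosomes = as.integer(n_chromosomes),
                   markers_per_chromosome = as.integer(markers_per_chromosome),
                   chromosome_length_bp = chromosome_length_bp,
                   n_founders = as.integer(n_founders),
                   n_generations = as.integer(n_generations),
                   matings_per_generation = as.integer(matings_per_generation),
                   offspring_per_mating = as.integer(offspring_per_mating),
                   founder_minor_allele_freq_range = rng,
                   founder_haplotype_pool = as.integer(founder_haplotype_pool),
                   lethal_loci = lethal_loci,
                   genotype_missing_rate = genotype_missing_rate,
                   genotype_error_rate = genotype_error_rate,
                   trio_fraction = trio_fraction,
                   recomb_cm_per_mb = recomb_cm_per_mb,
                   seed = as.integer(seed)),
              class = "sim_config")
}

#' Marker map implied by a simulation configuration
#' @param config a [sim_config()].
#' @return a [marker_map()].
#' @export
sim_marker_map <- function(config) {
    m <- config$markers_per_chromosome
    spacing <- floor(config$chromosome_length_bp / m)
    one <- spacing * seq_len(m)
    marker_map(
        marker_id = unlist(lapply(seq_len(config$n_chromosomes), function(c)
            sprintf("C%dM%05d", c, seq_len(m)))),
        chrom = rep(as.character(seq_len(config$n_chromosomes)), each = m),
        pos_bp = rep(one, config$n_chromosomes))
}

#' Column indices of a lethal locus span in the genome-wide matrix
#' @noRd
.locus_span_cols <- function(config, ll) {
    s <- ll$center_marker - ll$span_markers %/% 2L
    (ll$chromosome - 1L) * config$markers_per_chromosome +
        seq.int(s, s + ll$span_markers - 1L)
}

#' Simulate a pedigreed, genotyped population with embedded lethals
#'
#' Founder chromosomes are sampled from a limited haplotype pool;
#' descendants are produced by Mendelian gene drop with Poisson (Haldane)
#' crossovers. Each configured [lethal_locus()] overwrites one chromosome
#' copy of `round(target_carrier_frequency * n_founders)` founders with a
#' shared marker-allele segment; animals homozygous for that segment are,
#' with probability `penetrance`, removed at conception: they stay in the
#' pedigree but never reproduce and never reach the genotype matrix.
#'
#' @param config a [sim_config()].
#' @return A `sim_population` list with elements `pedigree` (all conceived
#'   animals), `haplotypes` (a [hap_matrix()] of genotyped survivors),
#'   `map`, `truth` (one row per lethal locus: span, tracked allele string,
#'   causal-variant position, realized counts), `removed_ids`, and
#'   `config`.
#' @export
simulate_population <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    set.seed(config$seed)
    map <- sim_marker_map(config)
    M <- nrow(map)
    mc <- config$markers_per_chromosome
    nF <- config$n_founders
    morgans <- map$pos_bp * 1e-8 * config$recomb_cm_per_mb
    chrom_cols <- lapply(seq_len(config$n_chromosomes), function(c)
        (c - 1L) * mc + seq_len(mc))

    n_total <- nF + config$n_generations * config$matings_per_generation *
        config$offspring_per_mating
    ids <- sprintf("A%05d", seq_len(n_total))
    alleles <- matrix(NA_integer_, nrow = 2L * n_total, ncol = M)

    # founders: sample chromosomes from a per-chromosome haplotype pool
    for (cc in chrom_cols) {
        f <- runif(mc, config$founder_minor_allele_freq_range[1],
                   config$founder_minor_allele_freq_range[2])
        K <- config$founder_haplotype_pool
        if (K > 0L) {
            pool <- matrix(rbinom(K * mc, 1L, rep(f, each = K)), nrow = K)
            # keep every marker polymorphic in the pool, else the
            # configured founder frequency range is violated and the
            # marker would only fall to the MAF filter downstream
            fix0 <- which(colSums(pool) == 0L)
            if (length(fix0))
                pool[cbind(sample.int(K, length(fix0), replace = TRUE),
                           fix0)] <- 1L
            fix1 <- which(colSums(pool) == K)
            if (length(fix1))
                pool[cbind(sample.int(K, length(fix1), replace = TRUE),
                           fix1)] <- 0L
            pick <- sample.int(K, 2L * nF, replace = TRUE)
            alleles[seq_len(2L * nF), cc] <- pool[pick, , drop = FALSE]
        } else {
            alleles[seq_len(2L * nF), cc] <-
                matrix(rbinom(2L * nF * mc, 1L,
                              rep(f, each = 2L * nF)), nrow = 2L * nF)
        }
    }

    # inject lethal haplotype segments into founder chromosomes
    truth_hap <- vector("list", length(config$lethal_loci))
    truth_founders <- integer(length(config$lethal_loci))
    for (i in seq_along(config$lethal_loci)) {
        ll <- config$lethal_loci[[i]]
        ncf <- round(ll$target_carrier_frequency * nF)
        if (ncf < 1L)
            .stopf(paste0("lethal locus %d: target carrier frequency %.3f ",
                          "is unreachable with %d founders"),
                   i, ll$target_carrier_frequency, nF)
        span <- .locus_span_cols(config, ll)
        repeat {
            hstr <- rbinom(length(span), 1L, 0.5)
            hits <- colSums(t(alleles[seq_len(2L * nF), span, drop = FALSE]) ==
                            hstr) == length(span)
            if (!any(hits)) break
        }
        carriers <- sample.int(nF, ncf)
        alleles[2L * carriers - 1L, span] <-
            matrix(hstr, nrow = ncf, ncol = length(span), byrow = TRUE)
        truth_hap[[i]] <- hstr
        truth_founders[i] <- ncf
    }

    sex <- character(n_total)
    sex[seq_len(nF)] <- rep_len(c("M", "F"), nF)
    sire <- rep("0", n_total)
    dam <- rep("0", n_total)
    generation <- integer(n_total)
    dead <- logical(n_total)
    n_removed_locus <- integer(length(config$lethal_loci))
    removed <- character(0)
    n_done <- nF

    .is_hom <- function(rows_idx, span, hstr) {
        # rows_idx: animal indices; TRUE when both haplotypes match hstr
        r1 <- alleles[2L * rows_idx - 1L, span, drop = FALSE]
        r2 <- alleles[2L * rows_idx, span, drop = FALSE]
        m1 <- rowSums(r1 == matrix(hstr, nrow(r1), length(span),
                                   byrow = TRUE)) == length(span)
        m2 <- rowSums(r2 == matrix(hstr, nrow(r2), length(span),
                                   byrow = TRUE)) == length(span)
        m1 & m2
    }

    for (g in seq_len(config$n_generations)) {
        pool <- which(!dead[seq_len(n_done)])
        males <- pool[sex[pool] == "M"]
        females <- pool[sex[pool] == "F"]
        if (!length(males) || !length(females))
            .stopf("generation %d: no surviving %s to mate", g,
                   if (!length(males)) "males" else "females")
        nm <- config$matings_per_generation
        sires_g <- males[sample.int(length(males), nm, replace = TRUE)]
        dams_g <- females[sample.int(length(females), nm, replace = TRUE)]
        n_off <- nm * config$offspring_per_mating
        off <- n_done + seq_len(n_off)
        off_sire <- rep(sires_g, each = config$offspring_per_mating)
        off_dam <- rep(dams_g, each = config$offspring_per_mating)
        sire[off] <- ids[off_sire]
        dam[off] <- ids[off_dam]
        generation[off] <- g
        sex[off] <- c("M", "F")[1L + (runif(n_off) < 0.5)]
        for (cc in chrom_cols) {
            pat <- drop_gametes_cpp(alleles[, cc, drop = FALSE],
                                    2L * off_sire - 2L, 2L * off_sire - 1L,
                                    morgans[cc])
            mat <- drop_gametes_cpp(alleles[, cc, drop = FALSE],
                                    2L * off_dam - 2L, 2L * off_dam - 1L,
                                    morgans[cc])
            alleles[2L * off - 1L, cc] <- pat
            alleles[2L * off, cc] <- mat
        }
        for (i in seq_along(config$lethal_loci)) {
            ll <- config$lethal_loci[[i]]
            hom <- .is_hom(off, .locus_span_cols(config, ll), truth_hap[[i]])
            die <- hom & (runif(n_off) < ll$penetrance)
            n_removed_locus[i] <- n_removed_locus[i] + sum(die)
            dead[off[die]] <- TRUE
        }
        removed <- c(removed, ids[off][dead[off]])
        n_done <- n_done + n_off
    }

    genotyped <- !dead & (sex == "M" | runif(n_total) < config$trio_fraction)

    gidx <- which(genotyped)
    galleles <- alleles[.animal_rows(gidx), , drop = FALSE]
    ng <- length(gidx)

    # post-phasing allele flips (array/imputation error stand-in)
    if (config$genotype_error_rate > 0 && ng > 0) {
        hit <- which(matrix(runif(ng * M) < config$genotype_error_rate,
                            nrow = ng))
        if (length(hit)) {
            a <- (hit - 1L) %% ng + 1L        # animal index
            m <- (hit - 1L) %/% ng + 1L       # marker index
            row <- 2L * a - 1L + (runif(length(hit)) < 0.5)
            flat <- row + (m - 1L) * nrow(galleles)
            galleles[flat] <- 1L - galleles[flat]
        }
    }
    if (config$genotype_missing_rate > 0 && ng > 0) {
        miss <- matrix(runif(ng * M) < config$genotype_missing_rate,
                       nrow = ng)
        both <- miss[rep(seq_len(ng), each = 2L), , drop = FALSE]
        galleles[both] <- NA_integer_
    }

    haps <- hap_matrix(ids[gidx], galleles, phased = TRUE)

    truth <- NULL
    if (length(config$lethal_loci)) {
        rows <- lapply(seq_along(config$lethal_loci), function(i) {
            ll <- config$lethal_loci[[i]]
            span <- .locus_span_cols(config, ll)
            center_bp <- map$pos_bp[(ll$chromosome - 1L) * mc +
                                    ll$center_marker]
            vpos <- min(max(1, center_bp + ll$linked_variant_offset_bp),
                        config$chromosome_length_bp)
            dos <- window_dosage_cpp(
                haps$alleles[, span, drop = FALSE], truth_hap[[i]])
            data.frame(locus_id = sprintf("L%d", i),
                       chrom = as.character(ll$chromosome),
                       span_start_marker = span[1] - (ll$chromosome - 1L) * mc,
                       span_end_marker =
                           span[length(span)] - (ll$chromosome - 1L) * mc,
                       span_start_bp = map$pos_bp[span[1]],
                       span_end_bp = map$pos_bp[span[length(span)]],
                       variant_pos_bp = vpos,
                       penetrance = ll$penetrance,
                       target_carrier_frequency = ll$target_carrier_frequency,
                       hap = paste(truth_hap[[i]], collapse = ""),
                       n_carrier_founders = truth_founders[i],
                       n_removed = n_removed_locus[i],
                       n_carriers_genotyped = sum(dos == 1L, na.rm = TRUE),
                       n_homozygotes_genotyped = sum(dos == 2L, na.rm = TRUE),
                       stringsAsFactors = FALSE)
        })
        truth <- do.call(rbind, rows)
        no_carrier <- truth$locus_id[truth$n_carriers_genotyped == 0L]
        if (length(no_carrier))
            .stopf("no surviving genotyped carrier for lethal locus %s",
                   paste(no_carrier, collapse = ", "))
    }

    structure(list(
        pedigree = pedigree(ids, sire, dam, sex),
        haplotypes = haps,
        map = map,
        truth = truth,
        removed_ids = removed,
        generation = setNames(generation, ids),
        config = config), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
    cat(sprintf(paste0("<sim_population> %d conceived, %d genotyped, ",
                       "%d removed by lethality, %d markers, %d lethal ",
                       "locus/loci\n"),
                nrow(x$pedigree), length(x$haplotypes$ids),
                length(x$removed_ids), nrow(x$map),
                length(x$config$lethal_loci)))
    invisible(x)
}

#' Remove homozygotes for a tracked lethal haplotype
#'
#' Applies (additional) lethality to an existing population: every
#' genotyped animal homozygous for the tracked segment of `spec` is
#' removed from the genotype matrix with probability `spec$penetrance`.
#' Heterozygotes and non-carriers are untouched. Used for post-hoc
#' penetrance experiments; [simulate_population()] already applies the
#' configured penetrance at conception.
#'
#' @param population a `sim_population`.
#' @param spec a [lethal_locus()] matching one of the population's truth
#'   loci (same chromosome and centre marker).
#' @return The modified `sim_population`.
#' @export
apply_lethality <- function(population, spec) {
    stopifnot(inherits(population, "sim_population"),
              inherits(spec, "lethal_locus"))
    cfg <- population$config
    truth <- population$truth
    if (is.null(truth)) .stopf("population has no tracked lethal loci")
    s <- spec$center_marker - spec$span_markers %/% 2L
    hit <- which(truth$chrom == as.character(spec$chromosome) &
                 truth$span_start_marker == s)
    if (!length(hit))
        .stopf("no tracked haplotype at chromosome %s marker %d",
               spec$chromosome, spec$center_marker)
    hit <- hit[1L]
    span <- .locus_span_cols(cfg, spec)
    hstr <- as.integer(strsplit(truth$hap[hit], "")[[1]])
    dos <- window_dosage_cpp(
        population$haplotypes$alleles[, span, drop = FALSE], hstr)
    hom <- which(!is.na(dos) & dos == 2L)
    die <- hom[runif(length(hom)) < spec$penetrance]
    if (length(die)) {
        gone <- population$haplotypes$ids[die]
        population$haplotypes <- subset_hap(
            population$haplotypes,
            animals = setdiff(population$haplotypes$ids, gone))
        population$removed_ids <- c(population$removed_ids, gone)
        population$truth$n_removed[hit] <-
            population$truth$n_removed[hit] + length(die)
        population$truth$n_homozygotes_genotyped[hit] <-
            population$truth$n_homozygotes_genotyped[hit] - length(die)
    }
    population
}

#' Attach a sequenced panel with one causal variant per lethal locus
#'
#' Emulates whole-genome sequencing of selected carriers: for each tracked
#' locus the panel receives one protein-changing causal variant whose
#' genotype dosage equals the animal's diplotype dosage for the tracked
#' haplotype (perfect co-segregation, r^2 = 1 by construction), plus
#' `n_background_variants` unlinked variants with random dosages and mixed
#' consequence annotations. The panel contains `n_carriers` heterozygous
#' carriers per locus plus `n_noncarriers` animals carrying no copy.
#'
#' @param population a `sim_population` with at least one lethal locus.
#' @param n_carriers sequenced carriers per locus (default 3, the usual
#'   per-haplotype sequencing depth in such screens).
#' @param n_background_variants unlinked variants to add.
#' @param n_noncarriers non-carrier animals added to the panel.
#' @return A `seq_panel` list: `variants` data frame (with `causal` flag
#'   and `locus_id`), `dosages` matrix (variants x samples) and `samples`.
#' @export
attach_sequence_panel <- function(population, n_carriers = 3L,
                                  n_background_variants = 50L,
                                  n_noncarriers = 2L) {
    stopifnot(inherits(population, "sim_population"),
              .is_count(n_carriers, 1L), .is_count(n_background_variants),
              .is_count(n_noncarriers, 0L))
    truth <- population$truth
    if (is.null(truth)) .stopf("population has no tracked lethal loci")
    cfg <- population$config
    haps <- population$haplotypes
    mc <- cfg$markers_per_chromosome

    dosage_for <- function(i) {
        span <- (as.integer(truth$chrom[i]) - 1L) * mc +
            seq.int(truth$span_start_marker[i], truth$span_end_marker[i])
        hstr <- as.integer(strsplit(truth$hap[i], "")[[1]])
        window_dosage_cpp(haps$alleles[, span, drop = FALSE], hstr)
    }
    dos_all <- lapply(seq_len(nrow(truth)), dosage_for)

    samples <- character(0)
    for (i in seq_len(nrow(truth))) {
        d <- dos_all[[i]]
        het <- haps$ids[!is.na(d) & d == 1L]
        if (length(het) < n_carriers)
            .stopf("locus %s: only %d heterozygous carriers, %d requested",
                   truth$locus_id[i], length(het), n_carriers)
        samples <- c(samples, het[sample.int(length(het), n_carriers)])
    }
    non <- haps$ids[Reduce(`&`, lapply(dos_all, function(d)
        !is.na(d) & d == 0L))]
    if (n_noncarriers > 0L) {
        if (!length(non)) .stopf("no complete non-carrier available for panel")
        samples <- c(samples,
                     non[sample.int(length(non),
                                    min(n_noncarriers, length(non)))])
    }
    samples <- sort(unique(samples))
    sidx <- match(samples, haps$ids)

    csq_cycle <- c("frameshift_variant", "missense_variant", "stop_gained")
    causal <- lapply(seq_len(nrow(truth)), function(i) {
        data.frame(chrom = truth$chrom[i], pos = truth$variant_pos_bp[i],
                   ref = "A", alt = "T",
                   gene = sprintf("GENE%02d", i),
                   transcript = sprintf("TX%02d.1", i),
                   consequence = csq_cycle[(i - 1L) %% 3L + 1L],
                   c_dot = sprintf("c.%dT>A", 900 + i),
                   causal = TRUE, locus_id = truth$locus_id[i],
                   stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, causal)
    dosages <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
        dos_all[[i]][sidx]))

    if (n_background_variants > 0L) {
        bg_csq <- c("synonymous_variant", "intron_variant",
                    "intergenic_region", "missense_variant",
                    "3_prime_UTR_variant", "upstream_gene_variant",
                    "stop_gained", "splice_region_variant")
        bchrom <- as.character(sample.int(cfg$n_chromosomes,
                                          n_background_variants,
                                          replace = TRUE))
        bpos <- sample.int(cfg$chromosome_length_bp, n_background_variants)
        af <- runif(n_background_variants, 0.05, 0.5)
        bdos <- matrix(rbinom(n_background_variants * length(samples), 2L,
                              rep(af, length(samples))),
                       nrow = n_background_variants)
        bg <- data.frame(chrom = bchrom, pos = bpos, ref = "G", alt = "C",
                         gene = sprintf("BG%04d",
                                        seq_len(n_background_variants)),
                         transcript = sprintf("BGTX%04d.1",
                                              seq_len(n_background_variants)),
                         consequence = sample(bg_csq, n_background_variants,
                                              replace = TRUE),
                         c_dot = NA_character_,
                         causal = FALSE, locus_id = NA_character_,
                         stringsAsFactors = FALSE)
        clash <- paste(bg$chrom, bg$pos) %in%
            paste(variants$chrom, variants$pos)
        variants <- rbind(variants, bg[!clash, , drop = FALSE])
        dosages <- rbind(dosages, bdos[!clash, , drop = FALSE])
    }

    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord, , drop = FALSE]
    dosages <- dosages[ord, , drop = FALSE]
    rownames(variants) <- NULL
    dimnames(dosages) <- list(NULL, samples)
    structure(list(variants = variants, dosages = dosages,
                   samples = samples), class = "seq_panel")
}

#' Export a simulated population as standard text files
#'
#' Writes `genotypes.vcf` (phased VCF 4.2), `pedigree.tsv`,
#' `marker_map.tsv` and, when lethal loci are tracked, `truth.tsv`.
#' Loading the VCF and pedigree back with [load_dataset()] reproduces the
#' allele matrix and pedigree exactly.
#'
#' @param population a `sim_population`.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_population <- function(population, out_dir) {
    stopifnot(inherits(population, "sim_population"))
    if (!length(population$haplotypes$ids))
        .stopf("population has no genotyped animals to export")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lens <- setNames(rep(population$config$chromosome_length_bp,
                         population$config$n_chromosomes),
                     as.character(seq_len(population$config$n_chromosomes)))
    paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
               pedigree = file.path(out_dir, "pedigree.tsv"),
               map = file.path(out_dir, "marker_map.tsv"),
               truth = file.path(out_dir, "truth.tsv"))
    write_phased_vcf(population$haplotypes, population$map, paths["vcf"],
                     chrom_lengths = lens)
    write_pedigree_tsv(population$pedigree, paths["pedigree"])
    write_marker_map_tsv(population$map, paths["map"])
    if (!is.null(population$truth)) {
        write.table(population$truth, paths["truth"], sep = "\t",
                    quote = FALSE, row.names = FALSE)
    } else {
        paths <- paths[names(paths) != "truth"]
    }
    invisible(paths)
}
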