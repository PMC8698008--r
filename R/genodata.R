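#' Load a phased VCF and a pedigree file
#'
#' Reads biallelic SNP genotypes (GT field) into a [hap_matrix()] plus
#' [marker_map()] and the pedigree TSV into a validated [pedigree()].
#' Animals whose every called genotype uses the `|` separator are flagged
#' phased; a single `/`-separated call marks the animal unphased (missing
#' genotypes are neutral). Multi-allelic records and duplicate marker ids
#' are rejected with the offending record named; coordinates are kept
#' 1-based as in the VCF.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF 4.x file.
#' @param pedigree_path path to a TSV with columns
#'   `animal_id sire_id dam_id sex` (`"0"` = unknown).
#' @return A list with elements `haplotypes`, `map`, `pedigree`.
#' @export
load_dataset <- function(vcf_path, pedigree_path) {
    if (!file.exists(vcf_path)) .stopf("VCF not found: %s", vcf_path)
    ped <- read_pedigree_tsv(pedigree_path)
    vt <- .read_vcf_table(vcf_path)
    body <- vt$body
    ids <- body$ID
    noid <- ids == "." | ids == ""
    ids[noid] <- paste0(body$`#CHROM`[noid], ":", body$POS[noid])
    multi <- grepl(",", body$ALT, fixed = TRUE)
    if (any(multi))
        .stopf("multi-allelic record(s): %s",
               paste(utils::head(ids[multi], 5L), collapse = ", "))
    gt <- .vcf_gt_matrix(body, vcf_path)
    map <- marker_map(ids, body$`#CHROM`, as.numeric(body$POS))
    n <- ncol(gt)
    m <- nrow(gt)
    a1c <- substr(gt, 1L, 1L)
    a2c <- substr(gt, 3L, 3L)
    sep <- substr(gt, 2L, 2L)
    to_int <- function(x) {
        out <- rep(NA_integer_, length(x))
        out[x == "0"] <- 0L
        out[x == "1"] <- 1L
        bad <- !(x %in% c("0", "1", ".", ""))
        if (any(bad))
            .stopf("unsupported allele code '%s' (biallelic 0/1 expected)",
                   x[bad][1L])
        out
    }
    a1 <- matrix(to_int(a1c), nrow = m)
    a2 <- matrix(to_int(a2c), nrow = m)
    called <- !(is.na(a1) | is.na(a2))
    unph <- (sep == "/") & called
    phased <- colSums(unph) == 0L
    alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
    alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
    alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)
    haps <- hap_matrix(colnames(gt), alleles, phased = phased)
    list(haplotypes = haps, map = map, pedigree = ped)
}

#' Quality-control thresholds
#'
#' Defaults follow routine SNP-array QC for this kind of screen: markers
#' with minor allele frequency below 1% are excluded, the per-SNP call
#' rate must exceed 0.99, and animals with call rates below 0.8 are
#' excluded.
#'
#' @param min_maf minimum minor allele frequency (marker kept when
#'   `MAF >= min_maf`).
#' @param min_snp_call_rate marker kept when call rate `> min_snp_call_rate`.
#' @param min_animal_call_rate animal kept when call rate
#'   `>= min_animal_call_rate`.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_maf = 0.01, min_snp_call_rate = 0.99,
                          min_animal_call_rate = 0.8) {
    for (p in c(min_maf, min_snp_call_rate, min_animal_call_rate))
        if (!.is_prob(p)) .stopf("QC thresholds must lie in [0, 1]")
    structure(list(min_maf = min_maf,
                   min_snp_call_rate = min_snp_call_rate,
                   min_animal_call_rate = min_animal_call_rate),
              class = "qc_thresholds")
}

#' Quality-filter a haplotype matrix
#'
#' Filters are applied in a fixed, documented order, each recomputed on
#' the surviving set: (1) animal call rate, (2) SNP call rate, (3) minor
#' allele frequency. MAF is computed on called alleles only (missing
#' alleles are excluded from the denominator). The report lists every
#' removed animal/marker with the reason, the offending value and the
#' threshold.
#'
#' @param matrix a [hap_matrix()].
#' @param map the aligned [marker_map()].
#' @param thresholds a [qc_thresholds()].
#' @return list(`haplotypes`, `map`, `report`); `report` is a data frame
#'   with columns `entity type reason value threshold`.
#' @export
qc_filter <- function(matrix, map, thresholds = qc_thresholds()) {
    stopifnot(inherits(matrix, "hap_matrix"),
              inherits(thresholds, "qc_thresholds"))
    validate_marker_map(map)
    if (nrow(map) != ncol(matrix$alleles))
        .stopf("map does not match matrix")
    report <- data.frame(entity = character(0), type = character(0),
                         reason = character(0), value = numeric(0),
                         threshold = numeric(0), stringsAsFactors = FALSE)
    # 1. animal call rate
    acr <- animal_call_rate(matrix)
    drop_a <- which(acr < thresholds$min_animal_call_rate)
    if (length(drop_a)) {
        report <- rbind(report, data.frame(
            entity = names(acr)[drop_a], type = "animal",
            reason = "low_call_rate", value = unname(acr[drop_a]),
            threshold = thresholds$min_animal_call_rate))
        matrix <- subset_hap(matrix,
                             animals = setdiff(matrix$ids, names(acr)[drop_a]))
    }
    n <- n_animals(matrix)
    odd <- matrix$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    even <- matrix$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    called <- !(is.na(odd) | is.na(even))
    # 2. SNP call rate on surviving animals
    scr <- colMeans(called)
    drop_s <- which(scr <= thresholds$min_snp_call_rate & scr < 1)
    if (length(drop_s)) {
        report <- rbind(report, data.frame(
            entity = map$marker_id[drop_s], type = "marker",
            reason = "low_call_rate", value = unname(scr[drop_s]),
            threshold = thresholds$min_snp_call_rate))
        keep <- setdiff(seq_len(ncol(matrix$alleles)), drop_s)
        matrix <- subset_hap(matrix, markers = keep)
        map <- map[keep, , drop = FALSE]
        odd <- odd[, keep, drop = FALSE]
        even <- even[, keep, drop = FALSE]
    }
    # 3. MAF on called alleles of surviving animals and markers
    ones <- colSums(odd == 1L, na.rm = TRUE) + colSums(even == 1L, na.rm = TRUE)
    tot <- colSums(!is.na(odd)) + colSums(!is.na(even))
    af <- ifelse(tot > 0, ones / tot, 0)
    maf <- pmin(af, 1 - af)
    drop_m <- which(maf < thresholds$min_maf)
    if (length(drop_m)) {
        report <- rbind(report, data.frame(
            entity = map$marker_id[drop_m], type = "marker",
            reason = "low_maf", value = unname(maf[drop_m]),
            threshold = thresholds$min_maf))
        keep <- setdiff(seq_len(ncol(matrix$alleles)), drop_m)
        matrix <- subset_hap(matrix, markers = keep)
        map <- map[keep, , drop = FALSE]
    }
    if (ncol(matrix$alleles) == 0L)
        .stopf("QC removed every marker; check thresholds and input data")
    rownames(report) <- NULL
    list(haplotypes = matrix, map = map, report = report)
}

#' Build trio and parent-grandparent (pgp) analysis cohorts
#'
#' A trio requires offspring, sire and dam all genotyped. A pgp group
#' requires offspring, sire and maternal grandsire (the dam's sire)
#' genotyped; the dam herself need not be. An offspring may appear in
#' both cohorts unless `disjoint = TRUE`, in which case trio membership
#' wins and such offspring are dropped from the pgp set.
#'
#' @param pedigree a [pedigree()].
#' @param genotyped_ids character vector of genotyped animal ids.
#' @param disjoint drop trio offspring from the pgp cohort?
#' @return list(`trios`, `pgp`) of data frames (`offspring`, `sire`,
#'   `dam` / `mgs`), class `cohort_sets`.
#' @export
build_cohorts <- function(pedigree, genotyped_ids, disjoint = FALSE) {
    validate_pedigree(pedigree)
    g <- unique(as.character(genotyped_ids))
    sire_of <- setNames(pedigree$sire_id, pedigree$animal_id)
    off_g <- pedigree$animal_id %in% g
    sire_g <- pedigree$sire_id != "0" & pedigree$sire_id %in% g
    dam_known <- pedigree$dam_id != "0"
    dam_g <- dam_known & pedigree$dam_id %in% g
    trio_sel <- off_g & sire_g & dam_g
    trios <- data.frame(offspring = pedigree$animal_id[trio_sel],
                        sire = pedigree$sire_id[trio_sel],
                        dam = pedigree$dam_id[trio_sel],
                        stringsAsFactors = FALSE)
    mgs <- rep(NA_character_, nrow(pedigree))
    mgs[dam_known] <- sire_of[pedigree$dam_id[dam_known]]
    pgp_sel <- off_g & sire_g & !is.na(mgs) & mgs != "0" & mgs %in% g
    pgp <- data.frame(offspring = pedigree$animal_id[pgp_sel],
                      sire = pedigree$sire_id[pgp_sel],
                      mgs = mgs[pgp_sel],
                      stringsAsFactors = FALSE)
    if (disjoint) pgp <- pgp[!(pgp$offspring %in% trios$offspring), ,
                             drop = FALSE]
    rownames(trios) <- rownames(pgp) <- NULL
    structure(list(trios = trios, pgp = pgp), class = "cohort_sets")
}

#' @export
print.cohort_sets <- function(x, ...) {
    cat(sprintf("<cohort_sets> %d trios, %d pgp groups\n",
                nrow(x$trios), nrow(x$pgp)))
    invisible(x)
}

#' Mendelian trio phasing
#'
#' Resolves the phase of heterozygous offspring genotypes from parental
#' homozygosity: when at least one genotyped parent is homozygous at a
#' site, the transmitted alleles are forced and the offspring's two rows
#' are ordered paternal-first. Genotypes are never altered, only the
#' within-animal row order. Sites where both parents are heterozygous (or
#' a needed parent is missing) stay unresolved and are flagged;
#' Mendelian-inconsistent sites (e.g. offspring `1/1` under a `0/0`
#' parent) are flagged, counted in the report attribute, and left alone.
#' Animals without both parents in the matrix are left unphased.
#'
#' @param matrix a [hap_matrix()] (typically with `phased = FALSE`).
#' @param pedigree a [pedigree()].
#' @return A [hap_matrix()] whose offspring are flagged phased, with
#'   unresolved sites recorded in `$unresolved` and a `report` attribute
#'   (`n_resolved`, `n_unresolved`, `n_mendel_errors`).
#' @export
trio_phase <- function(matrix, pedigree) {
    stopifnot(inherits(matrix, "hap_matrix"))
    validate_pedigree(pedigree)
    al <- matrix$alleles
    ids <- matrix$ids
    idx <- setNames(seq_along(ids), ids)
    phased <- matrix$phased
    unres_a <- integer(0)
    unres_m <- integer(0)
    n_resolved <- 0L
    n_mendel <- 0L
    ped <- pedigree[pedigree$animal_id %in% ids &
                    pedigree$sire_id %in% ids &
                    pedigree$dam_id %in% ids, , drop = FALSE]
    for (k in seq_len(nrow(ped))) {
        o <- idx[[ped$animal_id[k]]]
        s <- idx[[ped$sire_id[k]]]
        d <- idx[[ped$dam_id[k]]]
        o1 <- al[2L * o - 1L, ]; o2 <- al[2L * o, ]
        s1 <- al[2L * s - 1L, ]; s2 <- al[2L * s, ]
        d1 <- al[2L * d - 1L, ]; d2 <- al[2L * d, ]
        og <- o1 + o2   # offspring genotype dosage; NA if missing
        sg <- s1 + s2
        dg <- d1 + d2
        het <- !is.na(og) & og == 1L
        # Mendelian consistency where all three genotypes are called
        full <- !is.na(og) & !is.na(sg) & !is.na(dg)
        mend_bad <- full & (
            (og == 2L & (sg == 0L | dg == 0L)) |
            (og == 0L & (sg == 2L | dg == 2L)) |
            (og == 1L & ((sg == 0L & dg == 0L) | (sg == 2L & dg == 2L))))
        n_mendel <- n_mendel + sum(mend_bad)
        # paternal allele forced when the sire is homozygous, or when the
        # dam is homozygous (paternal = offspring genotype minus maternal)
        pat <- rep(NA_integer_, length(og))
        sire_hom <- !is.na(sg) & sg != 1L
        dam_hom <- !is.na(dg) & dg != 1L
        pat[sire_hom] <- sg[sire_hom] %/% 2L
        pat[!sire_hom & dam_hom] <- og[!sire_hom & dam_hom] -
            dg[!sire_hom & dam_hom] %/% 2L
        ok <- het & !mend_bad & !is.na(pat) & (pat == 0L | pat == 1L)
        if (any(ok)) {
            al[2L * o - 1L, ok] <- pat[ok]
            al[2L * o, ok] <- og[ok] - pat[ok]
            n_resolved <- n_resolved + sum(ok)
        }
        un <- which(het & !ok)
        if (length(un)) {
            unres_a <- c(unres_a, rep(o, length(un)))
            unres_m <- c(unres_m, un)
        }
        phased[o] <- TRUE
    }
    unresolved <- if (length(unres_a)) cbind(unres_a, unres_m) else NULL
    out <- hap_matrix(ids, al, phased, unresolved)
    attr(out, "report") <- list(n_resolved = n_resolved,
                                n_unresolved = length(unres_a),
                                n_mendel_errors = n_mendel)
    out
}
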