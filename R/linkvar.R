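#' Sequence Ontology terms counted as protein-changing
#'
#' The 14-term set used to restrict candidate-variant screening to
#' protein-changing annotations (SnpEff-style). Matching is exact and
#' case-sensitive on SO term strings.
#' @export
protein_changing_terms <- c(
    "missense_variant", "start_lost", "stop_gained", "stop_lost",
    "stop_retained_variant", "splice_acceptor_variant",
    "splice_donor_variant", "conservative_inframe_deletion",
    "conservative_inframe_insertion", "disruptive_inframe_deletion",
    "disruptive_inframe_insertion", "exon_loss_variant",
    "frameshift_variant", "gene_fusion")

#' Split a SnpEff-style consequence string into SO terms
#' @noRd
.csq_terms <- function(x) strsplit(x, "&", fixed = TRUE)

#' Keep protein-changing variants
#'
#' A variant is kept iff any of its consequence terms (several terms may
#' be joined by `&`, and several transcript annotations may be present)
#' is in [protein_changing_terms]. Order is preserved.
#'
#' @param variants data frame with a `consequence` column (and optionally
#'   an `ann` list-column of per-transcript annotations).
#' @return The qualifying subset of `variants`.
#' @export
consequence_filter <- function(variants) {
    stopifnot(is.data.frame(variants), "consequence" %in% names(variants))
    keep <- vapply(.csq_terms(variants$consequence), function(t)
        any(t %in% protein_changing_terms), logical(1))
    keep[is.na(keep)] <- FALSE
    variants[keep, , drop = FALSE]
}

#' Linkage disequilibrium between two genotype-dosage vectors
#'
#' r^2 is the squared Pearson correlation of the dosage vectors over
#' complete pairs — the diplotype-state vs WGS-genotype usage, computed on
#' 0/1/2 dosages rather than on phased gametes. When either vector is
#' constant (or fewer than two complete pairs remain), r^2 is undefined:
#' `r_squared` is `NA` and `defined` is `FALSE`, never silently 0.
#'
#' @param diplotypes dosage vector (0/1/2, `NA` allowed).
#' @param variant_dosages dosage vector aligned on the same samples.
#' @return list(`r_squared`, `n_samples`, `defined`).
#' @export
ld_r2 <- function(diplotypes, variant_dosages) {
    if (length(diplotypes) != length(variant_dosages))
        .stopf("dosage vectors differ in length (%d vs %d)",
               length(diplotypes), length(variant_dosages))
    ok <- !is.na(diplotypes) & !is.na(variant_dosages)
    x <- as.numeric(diplotypes[ok])
    y <- as.numeric(variant_dosages[ok])
    n <- length(x)
    if (n < 2L || stats::var(x) == 0 || stats::var(y) == 0)
        return(list(r_squared = NA_real_, n_samples = n, defined = FALSE))
    list(r_squared = stats::cor(x, y)^2, n_samples = n, defined = TRUE)
}

#' Screen a region's variants for perfectly linked candidates
#'
#' Pipeline: restrict variants to the region's extended interval, keep
#' protein-changing consequences, compute r^2 between the region's
#' diplotype dosages and each variant's genotype dosages over the panel,
#' and keep variants with `r^2 >= r2_threshold - tol`. For each candidate
#' the count of alt-allele homozygotes in the panel is reported — a
#' plausible recessive lethal never occurs in homozygous state.
#'
#' @param region one row of a `scan_regions` data frame (needs `chrom`,
#'   `ext_start_bp`, `ext_end_bp`, `region_id`).
#' @param diplotypes named dosage vector of the region's top haplotype for
#'   the panel samples (names = sample ids).
#' @param variants data frame as from [read_annotated_variants()] /
#'   [attach_sequence_panel()]: `chrom pos ref alt gene transcript
#'   consequence` (+ optional `c_dot`).
#' @param panel matrix of genotype dosages, variants x samples, rows
#'   aligned with `variants`.
#' @param r2_threshold minimum r^2 (default 1: perfect linkage).
#' @param tol tolerance absorbing floating-point noise on the threshold.
#' @return A `candidate_report` data frame: the qualifying variants with
#'   `r_squared`, `n_samples` and `panel_hom_count`, plus the region id.
#' @export
candidate_screen <- function(region, diplotypes, variants, panel,
                             r2_threshold = 1.0, tol = 1e-9) {
    stopifnot(is.data.frame(variants), is.matrix(panel),
              nrow(panel) == nrow(variants))
    if (!ncol(panel)) .stopf("empty sequencing panel")
    samp <- colnames(panel)
    if (is.null(samp) || is.null(names(diplotypes)))
        .stopf("panel columns and diplotypes must be named by sample id")
    common <- intersect(samp, names(diplotypes))
    if (!length(common)) .stopf("no shared samples between panel and diplotypes")
    inside <- variants$chrom == region$chrom &
        variants$pos >= region$ext_start_bp &
        variants$pos <= region$ext_end_bp
    v <- variants[inside, , drop = FALSE]
    m <- panel[inside, common, drop = FALSE]
    sel <- integer(0)
    if (nrow(v)) {
        v$.row <- seq_len(nrow(v))
        sel <- consequence_filter(v)$.row
        v$.row <- NULL
    }
    v <- v[sel, , drop = FALSE]
    m <- m[sel, , drop = FALSE]
    d <- diplotypes[common]
    res <- lapply(seq_len(nrow(v)), function(i) {
        ld <- ld_r2(d, m[i, ])
        data.frame(r_squared = ld$r_squared, n_samples = ld$n_samples,
                   defined = ld$defined,
                   panel_hom_count = sum(m[i, ] == 2L, na.rm = TRUE))
    })
    ld <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    out <- cbind(region_id = rep(region$region_id %||% NA_character_,
                                 nrow(v)),
                 v, ld)
    pass <- !is.na(out$r_squared) & out$r_squared >= r2_threshold - tol
    out <- out[pass, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("candidate_report", "data.frame")
    out
}

#' Codon number of a coding-sequence position
#'
#' Maps a 1-based coding nucleotide position (c. coordinate) to its
#' 1-based codon (amino-acid) number: `ceiling(pos / 3)`. E.g. c.2032
#' falls in codon 678 and c.938 in codon 313.
#'
#' @param cds_position 1-based coding nucleotide position(s).
#' @return Integer codon number(s).
#' @export
codon_index <- function(cds_position) {
    if (any(!is.finite(cds_position)) || any(cds_position < 1) ||
        any(cds_position != as.integer(cds_position)))
        .stopf("cds_position must be a positive integer")
    as.integer(ceiling(cds_position / 3))
}

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

#' Translate a coding sequence with the standard genetic code
#' @noRd
.translate_cds <- function(cds) {
    codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                        seq(3, nchar(cds), by = 3))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    unname(aa)
}

#' Protein consequence of a single-base duplication (frameshift)
#'
#' Duplicates the base at coding position `dup_position`, translates the
#' shifted frame, and reports the HGVS-style protein change
#' `p.<Ref><pos><Alt>Ter<k>`: the first altered residue and the offset of
#' the first stop codon in the new frame relative to it. A duplication of
#' c.2032 (an A) after an isoleucine codon with the next shifted codon
#' reading Asn and a stop immediately after gives `p.Ile678AsnTer2`-style
#' strings. If no stop is reached the offset is reported `Ter?`.
#'
#' @param cds wild-type coding sequence (A/C/G/T string, length divisible
#'   by 3, starting with ATG).
#' @param dup_position 1-based coding position of the duplicated base.
#' @return list(`codon`, `ref_aa`, `alt_aa`, `ter_offset`, `hgvs_p`,
#'   `fraction_lost` — fraction of wild-type residues lost, stop codon
#'   excluded).
#' @export
frameshift_consequence <- function(cds, dup_position) {
    cds <- toupper(gsub("[^ACGTacgt]", "", cds))
    n <- nchar(cds)
    if (n %% 3 != 0) .stopf("CDS length must be divisible by 3")
    if (substr(cds, 1, 3) != "ATG") .stopf("CDS must start with ATG")
    if (!.is_count(dup_position, 1L) || dup_position > n)
        .stopf("dup_position must lie in [1, %d]", n)
    wt <- .translate_cds(cds)
    mut_seq <- paste0(substr(cds, 1, dup_position),
                      substr(cds, dup_position, n))
    mut <- .translate_cds(substr(mut_seq, 1,
                                 3 * ((nchar(mut_seq)) %/% 3)))
    codon <- codon_index(dup_position)
    # first residue that differs from wild type, at or after the affected
    # codon (the duplication can leave the affected codon's residue intact)
    len <- min(length(wt), length(mut))
    diffpos <- which(wt[seq_len(len)] != mut[seq_len(len)])
    diffpos <- diffpos[diffpos >= codon]
    first <- if (length(diffpos)) diffpos[1L] else NA_integer_
    if (is.na(first)) {
        # frame restored / change confined to the stop region
        return(list(codon = codon, ref_aa = .aa3[[wt[codon]]],
                    alt_aa = .aa3[[wt[codon]]], ter_offset = NA_integer_,
                    hgvs_p = "p.(=)", fraction_lost = 0))
    }
    stop_pos <- which(mut == "*")
    stop_pos <- stop_pos[stop_pos >= first]
    ter <- if (length(stop_pos)) stop_pos[1L] - first + 1L else NA_integer_
    n_wt <- length(wt) - 1L                    # residues before the stop
    retained <- first - 1L
    list(codon = codon,
         ref_aa = .aa3[[wt[first]]],
         alt_aa = .aa3[[mut[first]]],
         ter_offset = ter,
         hgvs_p = sprintf("p.%s%d%s%s", .aa3[[wt[first]]], first,
                          .aa3[[mut[first]]],
                          if (is.na(ter)) "Ter?"
                          else if (mut[first] == "*") ""
                          else sprintf("Ter%d", ter)),
         fraction_lost = max(0, (n_wt - retained) / n_wt))
}
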