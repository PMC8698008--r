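#' Write a phased VCF 4.2 file
#'
#' One sample per animal, genotypes `a|b` for phased animals and `a/b` for
#' unphased ones; a genotype with any missing allele is written `./.`.
#' REF/ALT are fixed to A/C: the screen works on the 0/1 allele coding, not
#' on nucleotides. Output is deterministic, so identical inputs give
#' byte-identical files.
#'
#' @param hap a [hap_matrix()].
#' @param map a [marker_map()] aligned to `hap`.
#' @param path output file path.
#' @param chrom_lengths optional named vector of chromosome lengths (bp)
#'   for the `##contig` header lines; defaults to the last marker position.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hap, map, path, chrom_lengths = NULL) {
    validate_marker_map(map)
    if (nrow(map) != ncol(hap$alleles))
        .stopf("map (%d markers) does not match matrix (%d columns)",
               nrow(map), ncol(hap$alleles))
    n <- n_animals(hap)
    m <- nrow(map)
    chroms <- unique(map$chrom)
    if (is.null(chrom_lengths))
        chrom_lengths <- vapply(chroms, function(ch)
            max(map$pos_bp[map$chrom == ch]), numeric(1))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=haplodeficit",
             sprintf("##contig=<ID=%s,length=%s>", chroms,
                     format(chrom_lengths[chroms], scientific = FALSE,
                            trim = TRUE)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", hap$ids), collapse = "\t"))
    a1 <- t(hap$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE])
    a2 <- t(hap$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE])
    sep <- rep(ifelse(hap$phased, "|", "/"), each = m)
    gt <- matrix(paste0(ifelse(is.na(a1), ".", a1), sep,
                        ifelse(is.na(a2), ".", a2)), nrow = m)
    gt[is.na(a1) | is.na(a2)] <- "./."
    fixed <- data.frame(map$chrom,
                        format(map$pos_bp, scientific = FALSE, trim = TRUE),
                        map$marker_id, "A", "C", ".", "PASS", ".", "GT",
                        stringsAsFactors = FALSE)
    body <- do.call(paste, c(fixed, as.data.frame(gt), list(sep = "\t")))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write / read a pedigree TSV (`animal_id sire_id dam_id sex`, "0" unknown)
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @return `path` (writer) or a `pedigree` (reader).
#' @export
write_pedigree_tsv <- function(ped, path) {
    validate_pedigree(ped)
    write.table(as.data.frame(ped)[c("animal_id", "sire_id", "dam_id", "sex")],
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
    if (!file.exists(path)) .stopf("pedigree file not found: %s", path)
    pd <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = "character")
    need <- c("animal_id", "sire_id", "dam_id", "sex")
    if (!all(need %in% names(pd)))
        .stopf("pedigree file must have columns: %s", paste(need, collapse = " "))
    pedigree(pd$animal_id, pd$sire_id, pd$dam_id, pd$sex)
}

#' Write / read a marker map TSV (`marker_id chrom pos_bp`)
#' @param map a [marker_map()].
#' @param path file path.
#' @export
write_marker_map_tsv <- function(map, path) {
    validate_marker_map(map)
    out <- as.data.frame(map)
    out$pos_bp <- format(out$pos_bp, scientific = FALSE, trim = TRUE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname write_marker_map_tsv
#' @export
read_marker_map_tsv <- function(path) {
    if (!file.exists(path)) .stopf("marker map file not found: %s", path)
    mm <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = c("character", "character", "numeric"))
    marker_map(mm$marker_id, mm$chrom, mm$pos_bp)
}
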