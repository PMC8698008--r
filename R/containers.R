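#' Marker map
#'
#' A data frame of marker identifier, chromosome label and 1-based physical
#' position (bp). Positions must be strictly increasing within each
#' chromosome and identifiers unique.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome label per marker.
#' @param pos_bp 1-based physical position per marker.
#' @return A `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chrom, pos_bp) {
    mm <- data.frame(marker_id = as.character(marker_id),
                     chrom = as.character(chrom),
                     pos_bp = as.numeric(pos_bp),
                     stringsAsFactors = FALSE)
    class(mm) <- c("marker_map", "data.frame")
    validate_marker_map(mm)
}

#' @rdname marker_map
#' @param x object to validate.
#' @export
validate_marker_map <- function(x) {
    stopifnot(is.data.frame(x),
              all(c("marker_id", "chrom", "pos_bp") %in% names(x)))
    dup <- x$marker_id[duplicated(x$marker_id)]
    if (length(dup))
        .stopf("duplicate marker id(s): %s", paste(unique(dup), collapse = ", "))
    for (ch in unique(x$chrom)) {
        p <- x$pos_bp[x$chrom == ch]
        if (any(diff(p) <= 0))
            .stopf("positions not strictly increasing on chromosome %s", ch)
    }
    if (any(x$pos_bp < 1)) .stopf("positions must be >= 1 (1-based)")
    invisible(x)
}

#' Phased haplotype matrix
#'
#' Container for phased biallelic genotypes: an integer matrix with two
#' rows per animal (paternal then maternal haplotype where the phase source
#' distinguishes them) and one column per marker, alleles coded 0/1 with
#' `NA` for missing. A per-animal `phased` flag records whether the two
#' rows carry phase information; `unresolved` optionally lists
#' (animal index, marker index) pairs whose phase could not be resolved by
#' [trio_phase()].
#'
#' @param ids character vector of animal identifiers.
#' @param alleles integer matrix, `2 * length(ids)` rows.
#' @param phased logical vector per animal (recycled if length 1).
#' @param unresolved optional 2-column integer matrix of unresolved sites.
#' @return A `hap_matrix` object.
#' @export
hap_matrix <- function(ids, alleles, phased = TRUE, unresolved = NULL) {
    ids <- as.character(ids)
    if (!is.matrix(alleles)) .stopf("alleles must be a matrix")
    storage.mode(alleles) <- "integer"
    if (nrow(alleles) != 2L * length(ids))
        .stopf("allele matrix must have 2 rows per animal (%d ids, %d rows)",
               length(ids), nrow(alleles))
    if (anyDuplicated(ids)) .stopf("duplicate animal id(s)")
    bad <- alleles[!is.na(alleles) & !(alleles %in% c(0L, 1L))]
    if (length(bad)) .stopf("alleles must be coded 0/1/NA")
    phased <- rep_len(as.logical(phased), length(ids))
    structure(list(ids = ids, alleles = alleles, phased = phased,
                   unresolved = unresolved),
              class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
    cat(sprintf("<hap_matrix> %d animals x %d markers (%d phased)\n",
                length(x$ids), ncol(x$alleles), sum(x$phased)))
    invisible(x)
}

#' Number of animals / markers in a haplotype matrix
#' @param x a `hap_matrix`.
#' @export
n_animals <- function(x) length(x$ids)

#' @rdname n_animals
#' @export
n_markers <- function(x) ncol(x$alleles)

#' Row indices of an animal's two haplotypes
#' @noRd
.animal_rows <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

#' Subset a haplotype matrix by animals and/or markers
#'
#' @param x a `hap_matrix`.
#' @param animals animal ids (character) or indices to keep.
#' @param markers marker column indices to keep.
#' @return a `hap_matrix`.
#' @export
subset_hap <- function(x, animals = NULL, markers = NULL) {
    ai <- seq_along(x$ids)
    if (!is.null(animals)) {
        ai <- if (is.character(animals)) match(animals, x$ids) else animals
        if (anyNA(ai)) .stopf("unknown animal id(s): %s",
                              paste(animals[is.na(match(animals, x$ids))],
                                    collapse = ", "))
    }
    mi <- seq_len(ncol(x$alleles))
    if (!is.null(markers)) mi <- markers
    al <- x$alleles[.animal_rows(ai), mi, drop = FALSE]
    unres <- NULL
    if (!is.null(x$unresolved) && nrow(x$unresolved)) {
        a_new <- match(x$unresolved[, 1L], ai)
        m_new <- match(x$unresolved[, 2L], mi)
        keep <- !is.na(a_new) & !is.na(m_new)
        if (any(keep)) unres <- cbind(a_new[keep], m_new[keep])
    }
    hap_matrix(x$ids[ai], al, x$phased[ai], unres)
}

#' Per-animal genotype call rate
#'
#' A genotype is called when both alleles are non-missing.
#' @param x a `hap_matrix`.
#' @return named numeric vector, one call rate per animal.
#' @export
animal_call_rate <- function(x) {
    n <- n_animals(x)
    m <- ncol(x$alleles)
    odd <- x$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE]
    even <- x$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    called <- !(is.na(odd) | is.na(even))
    setNames(rowMeans(called), x$ids)
}

#' Pedigree
#'
#' Animal / sire / dam records with sex. `"0"` denotes an unknown parent.
#' Validation rejects parent loops (an animal that is its own ancestor)
#' and sex-inconsistent parent usage (an id used both as sire and as dam,
#' or used as a parent in conflict with its recorded sex).
#'
#' @param animal_id,sire_id,dam_id character vectors; `"0"` = unknown.
#' @param sex `"M"`, `"F"` or `"0"` (unknown).
#' @return A `pedigree` data frame.
#' @export
pedigree <- function(animal_id, sire_id, dam_id, sex = "0") {
    pd <- data.frame(animal_id = as.character(animal_id),
                     sire_id = as.character(sire_id),
                     dam_id = as.character(dam_id),
                     sex = rep_len(as.character(sex), length(animal_id)),
                     stringsAsFactors = FALSE)
    class(pd) <- c("pedigree", "data.frame")
    validate_pedigree(pd)
}

#' @rdname pedigree
#' @param x object to validate.
#' @export
validate_pedigree <- function(x) {
    stopifnot(is.data.frame(x),
              all(c("animal_id", "sire_id", "dam_id", "sex") %in% names(x)))
    dup <- x$animal_id[duplicated(x$animal_id)]
    if (length(dup))
        .stopf("duplicate pedigree record(s) for: %s",
               paste(unique(dup), collapse = ", "))
    if (!all(x$sex %in% c("M", "F", "0")))
        .stopf("sex must be one of M, F, 0")
    sires <- setdiff(unique(x$sire_id), "0")
    dams <- setdiff(unique(x$dam_id), "0")
    both <- intersect(sires, dams)
    if (length(both))
        .stopf("id(s) used both as sire and as dam: %s",
               paste(both, collapse = ", "))
    sx <- setNames(x$sex, x$animal_id)
    bad_sire <- sires[!is.na(sx[sires]) & sx[sires] == "F"]
    if (length(bad_sire))
        .stopf("female id(s) used as sire: %s", paste(bad_sire, collapse = ", "))
    bad_dam <- dams[!is.na(sx[dams]) & sx[dams] == "M"]
    if (length(bad_dam))
        .stopf("male id(s) used as dam: %s", paste(bad_dam, collapse = ", "))
    # cycle check: peel founders repeatedly (Kahn); leftovers form a cycle
    parents <- setNames(vector("list", nrow(x)), x$animal_id)
    for (i in seq_len(nrow(x)))
        parents[[i]] <- setdiff(c(x$sire_id[i], x$dam_id[i]), "0")
    resolved <- character(0)
    pending <- x$animal_id
    repeat {
        ok <- vapply(parents[pending], function(p)
            all(!(p %in% pending)), logical(1))
        if (all(!ok)) break
        resolved <- c(resolved, pending[ok])
        pending <- pending[!ok]
        if (!length(pending)) break
    }
    if (length(pending))
        .stopf("pedigree contains an ancestry loop involving: %s",
               paste(sort(pending), collapse = ", "))
    invisible(x)
}
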