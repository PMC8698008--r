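#' Merge significant scan windows into haplotype regions
#'
#' Significant (window, haplotype) records from one [scan()] run are
#' merged per approach and chromosome: windows sharing at least one
#' marker coalesce transitively into one region. Each region carries its
#' top haplotype — the member record with the lowest p-value, ties broken
#' by larger deficiency, then leftmost window start — and an extended
#' interval grown by `config$region_extension` on both sides, clipped to
#' `[1, chromosome end]`. Regions found by several approaches at
#' overlapping positions receive one shared `region_id` and are labelled
#' with all approaches that found them.
#'
#' @param records a `hap_scan` data frame from [scan()].
#' @param map the [marker_map()] used for the scan.
#' @param config the [scan_config()] used for the scan.
#' @param chrom_lengths optional named vector of chromosome lengths (bp)
#'   used for clipping; defaults to the last mapped marker position.
#' @return A `scan_regions` data frame, one row per (region, approach):
#'   `region_id approaches approach chrom start_idx end_idx start_bp
#'   end_bp length_mb ext_start_bp ext_end_bp n_windows` and the top
#'   haplotype's `hap n q observed expected deficiency p p_adj`.
#'   Empty input gives an empty frame (no error).
#' @export
build_regions <- function(records, map, config = scan_config(),
                          chrom_lengths = NULL) {
    validate_marker_map(map)
    sig <- records[records$significant, , drop = FALSE]
    empty <- data.frame(region_id = character(0), approaches = character(0),
                        approach = character(0), chrom = character(0),
                        start_idx = integer(0), end_idx = integer(0),
                        start_bp = numeric(0), end_bp = numeric(0),
                        length_mb = numeric(0), ext_start_bp = numeric(0),
                        ext_end_bp = numeric(0), n_windows = integer(0),
                        top_start_idx = integer(0), top_end_idx = integer(0),
                        top_start_bp = numeric(0), top_end_bp = numeric(0),
                        hap = character(0), n = integer(0), q = numeric(0),
                        observed = integer(0), expected = numeric(0),
                        deficiency = numeric(0), p = numeric(0),
                        p_adj = numeric(0), stringsAsFactors = FALSE)
    if (!nrow(sig)) {
        class(empty) <- c("scan_regions", "data.frame")
        return(empty)
    }
    if (is.null(chrom_lengths))
        chrom_lengths <- vapply(split(map$pos_bp, map$chrom), max, numeric(1))
    rows <- list()
    for (app in unique(sig$approach)) {
        for (ch in unique(sig$chrom[sig$approach == app])) {
            s <- sig[sig$approach == app & sig$chrom == ch, , drop = FALSE]
            s <- s[order(s$start_idx, s$end_idx), , drop = FALSE]
            grp <- cumsum(c(1L, as.integer(
                s$start_idx[-1L] > cummax(s$end_idx)[-nrow(s)])))
            for (g in unique(grp)) {
                m <- s[grp == g, , drop = FALSE]
                top <- m[order(m$p, -m$deficiency, m$start_idx), ][1L, ]
                st <- min(m$start_idx); en <- max(m$end_idx)
                rows[[length(rows) + 1L]] <- data.frame(
                    approach = app, chrom = ch,
                    start_idx = st, end_idx = en,
                    start_bp = map$pos_bp[st], end_bp = map$pos_bp[en],
                    length_mb = (map$pos_bp[en] - map$pos_bp[st]) / 1e6,
                    ext_start_bp = max(1, map$pos_bp[st] -
                                          config$region_extension),
                    ext_end_bp = min(chrom_lengths[[ch]],
                                     map$pos_bp[en] +
                                         config$region_extension),
                    n_windows = length(unique(m$start_idx)),
                    top_start_idx = top$start_idx,
                    top_end_idx = top$end_idx,
                    top_start_bp = map$pos_bp[top$start_idx],
                    top_end_bp = map$pos_bp[top$end_idx],
                    hap = top$hap, n = top$n, q = top$q,
                    observed = top$observed, expected = top$expected,
                    deficiency = top$deficiency, p = top$p,
                    p_adj = top$p_adj, stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out <- merge_region_sets(out)
    class(out) <- c("scan_regions", "data.frame")
    out
}

#' Assign shared region identifiers across approaches
#'
#' Rows (one per region and approach) whose physical intervals overlap on
#' the same chromosome are transitively grouped into one region and given
#' a common id (`SR1`, `SR2`, ... ordered by chromosome and position);
#' `approaches` lists every approach that found the region (e.g.
#' `"trio and pgp"`).
#'
#' @param regions data frame with columns `approach chrom start_bp end_bp`
#'   (one row per per-approach region), as built by [build_regions()].
#' @return The input with `region_id` and `approaches` columns prepended.
#' @export
merge_region_sets <- function(regions) {
    if (!nrow(regions)) {
        regions$region_id <- character(0)
        regions$approaches <- character(0)
        return(regions)
    }
    regions <- regions[order(regions$chrom, regions$start_bp,
                             regions$end_bp), , drop = FALSE]
    gid <- integer(nrow(regions))
    nid <- 0L
    for (ch in unique(regions$chrom)) {
        i <- which(regions$chrom == ch)
        grp <- cumsum(c(1L, as.integer(
            regions$start_bp[i][-1L] >
                cummax(regions$end_bp[i])[-length(i)])))
        gid[i] <- nid + grp
        nid <- max(gid[i])
    }
    # order groups by first appearance (chrom, position)
    uid <- unique(gid)
    region_id <- sprintf("SR%d", match(gid, uid))
    approaches <- vapply(gid, function(g)
        paste(sort(unique(regions$approach[gid == g]), decreasing = TRUE),
              collapse = " and "),
        character(1))
    cbind(data.frame(region_id = region_id, approaches = approaches,
                     stringsAsFactors = FALSE),
          regions, make.row.names = FALSE)
}

#' Write a region report TSV (one row per region and approach)
#'
#' Mirrors the usual published layout: observed/expected homozygotes,
#' integer percent deficiency, haplotype frequency and (adjusted)
#' p-values; unrounded values stay in the `scan_regions` object.
#'
#' @param regions a `scan_regions` data frame.
#' @param path output TSV path.
#' @param digits significant digits for p-values.
#' @return `path`, invisibly.
#' @export
write_region_report <- function(regions, path, digits = 4) {
    out <- data.frame(
        region_id = regions$region_id,
        approach = regions$approach,
        chrom = regions$chrom,
        start_bp = format(regions$start_bp, scientific = FALSE, trim = TRUE),
        end_bp = format(regions$end_bp, scientific = FALSE, trim = TRUE),
        length_mb = round(regions$length_mb, 2),
        observed = regions$observed,
        expected = round(regions$expected),
        deficiency_pct = round(regions$deficiency),
        freq = round(regions$q, 4),
        p = signif(regions$p, digits),
        p_adj = signif(regions$p_adj, digits),
        hap = regions$hap,
        top_start_bp = format(regions$top_start_bp, scientific = FALSE,
                              trim = TRUE),
        top_end_bp = format(regions$top_end_bp, scientific = FALSE,
                            trim = TRUE),
        ext_start_bp = format(regions$ext_start_bp, scientific = FALSE,
                              trim = TRUE),
        ext_end_bp = format(regions$ext_end_bp, scientific = FALSE,
                            trim = TRUE),
        stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export region intervals as BED (0-based, half-open)
#'
#' @param regions a `scan_regions` data frame.
#' @param path output BED path.
#' @param extended export the 2-Mb-extended intervals instead of the
#'   merged significant intervals?
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path, extended = FALSE) {
    st <- if (extended) regions$ext_start_bp else regions$start_bp
    en <- if (extended) regions$ext_end_bp else regions$end_bp
    bed <- data.frame(regions$chrom,
                      format(st - 1, scientific = FALSE, trim = TRUE),
                      format(en, scientific = FALSE, trim = TRUE),
                      paste(regions$region_id, regions$approach, sep = "_"))
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
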