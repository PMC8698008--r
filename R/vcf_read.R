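# Fast line-format VCF table reader.
#
# VariantAnnotation::readVcf/scanVcf parse an uncompressed multi-thousand-
# sample VCF through an R-level character path that took tens of seconds
# per load at this package's demo scale, dominating every pipeline run and
# the test suite. VCF bodies are plain tab-separated tables, so the reader
# below delegates the heavy lifting to data.table::fread and keeps only
# the VCF-specific header handling here. It intentionally supports the
# narrow contract the screen needs (biallelic SNP records with a GT field)
# and rejects anything else explicitly.

#' Read a VCF into header meta-lines and a body data frame
#' @noRd
.read_vcf_table <- function(path) {
    con <- file(path, "r")
    on.exit(close(con))
    meta <- character(0)
    repeat {
        l <- readLines(con, n = 1L)
        if (!length(l)) .stopf("no #CHROM header line in %s", path)
        if (startsWith(l, "#CHROM")) break
        if (!startsWith(l, "##")) .stopf("malformed VCF header in %s", path)
        meta <- c(meta, l)
    }
    body <- data.table::fread(path, sep = "\t", header = TRUE,
                              skip = "#CHROM", data.table = FALSE,
                              check.names = FALSE, colClasses = "character",
                              showProgress = FALSE)
    need <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
    if (!all(need %in% names(body)[seq_along(need)]))
        .stopf("malformed VCF column header in %s", path)
    list(meta = meta, body = body)
}

#' Extract a markers x samples GT matrix from a VCF body
#' @noRd
.vcf_gt_matrix <- function(body, path) {
    if (!("FORMAT" %in% names(body)) || ncol(body) < 10L)
        .stopf("VCF has no sample genotypes: %s", path)
    gt <- as.matrix(body[, -(1:9), drop = FALSE])
    fmt <- body$FORMAT
    if (!all(fmt == "GT")) {
        first <- vapply(strsplit(fmt, ":", fixed = TRUE), `[`, character(1), 1L)
        if (!all(first == "GT"))
            .stopf("VCF FORMAT must lead with GT: %s", path)
        gt[] <- sub(":.*$", "", gt)
    }
    gt
}
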