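#' Write a sequenced-panel VCF with SnpEff-style ANN annotations
#'
#' Genotypes are written unphased (`0/0`, `0/1`, `1/1`, `./.`) from the
#' dosage matrix; each record carries one `ANN` INFO entry in the SnpEff
#' field layout (allele | consequence | impact | gene | gene id | feature
#' type | feature id | biotype | rank | HGVS.c | HGVS.p | ...).
#'
#' @param panel a `seq_panel` from [attach_sequence_panel()].
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
    stopifnot(inherits(panel, "seq_panel"))
    v <- panel$variants
    gt_codes <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = nrow(v), ncol = length(panel$samples))
    ok <- !is.na(panel$dosages)
    gt[ok] <- gt_codes[panel$dosages[ok] + 1L]
    ann <- sprintf("ANN=%s|%s|MODIFIER|%s|%s|transcript|%s|protein_coding|1/1|%s||||||",
                   v$alt, v$consequence, v$gene, v$gene, v$transcript,
                   ifelse(is.na(v$c_dot), "", v$c_dot))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=haplodeficit",
             sprintf("##contig=<ID=%s>", unique(v$chrom)),
             paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=",
                    "\"Functional annotations: 'Allele | Annotation | ",
                    "Annotation_Impact | Gene_Name | Gene_ID | Feature_Type ",
                    "| Feature_ID | Transcript_BioType | Rank | HGVS.c | ",
                    "HGVS.p | cDNA | CDS | AA | Distance | Info'\">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"))
    fixed <- data.frame(v$chrom,
                        format(v$pos, scientific = FALSE, trim = TRUE),
                        sprintf("var%04d", seq_len(nrow(v))),
                        v$ref, v$alt, ".", "PASS", ann, "GT",
                        stringsAsFactors = FALSE)
    body <- do.call(paste, c(fixed, as.data.frame(gt), list(sep = "\t")))
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read annotated variants and genotype dosages from a VCF
#'
#' Accepts a VCF with a SnpEff-dialect `ANN` INFO field. Every annotation
#' entry's consequence terms are collected per variant (terms of several
#' transcripts joined by `&`, preserving SnpEff's own `&`-joined
#' multi-term entries); gene, transcript and HGVS.c of the first
#' annotation are kept as convenience columns. Genotype dosages are the
#' alt-allele counts, `NA` for missing calls.
#'
#' @param path VCF file path.
#' @return list(`variants` data frame, `dosages` matrix, `samples`),
#'   class `seq_panel`.
#' @export
read_annotated_variants <- function(path) {
    if (!file.exists(path)) .stopf("variant file not found: %s", path)
    vt <- .read_vcf_table(path)
    body <- vt$body
    ann_str <- rep(NA_character_, nrow(body))
    has <- grepl("(^|;)ANN=", body$INFO)
    if (!any(grepl("^##INFO=<ID=ANN", vt$meta)) && !any(has))
        .stopf(paste0("VCF lacks the ANN INFO field required for ",
                      "consequence filtering; provide SnpEff-style ",
                      "annotation or a sidecar TSV"))
    ann_str[has] <- sub(".*(?:^|;)ANN=([^;]*).*", "\\1", body$INFO[has],
                        perl = TRUE)
    parse_one <- function(s) {
        if (is.na(s))
            return(list(consequence = NA_character_, gene = NA_character_,
                        transcript = NA_character_, c_dot = NA_character_))
        # SnpEff separates transcript annotations by "," and subfields by
        # "|"; several SO terms within one annotation stay "&"-joined
        parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "|",
                          fixed = TRUE)
        list(consequence = paste(unique(unlist(lapply(parts, `[`, 2L))),
                                 collapse = "&"),
             gene = parts[[1L]][4L],
             transcript = parts[[1L]][7L],
             c_dot = if (length(parts[[1L]]) >= 10L &&
                         nzchar(parts[[1L]][10L])) parts[[1L]][10L]
                     else NA_character_)
    }
    parsed <- lapply(ann_str, parse_one)
    gt <- .vcf_gt_matrix(body, path)
    dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = list(NULL, colnames(gt)))
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    called <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
    dos[called] <- (a1 == "1")[called] + (a2 == "1")[called]
    variants <- data.frame(
        chrom = body$`#CHROM`,
        pos = as.numeric(body$POS),
        ref = body$REF,
        alt = vapply(strsplit(body$ALT, ",", fixed = TRUE), `[`,
                     character(1), 1L),
        gene = vapply(parsed, `[[`, character(1), "gene"),
        transcript = vapply(parsed, `[[`, character(1), "transcript"),
        consequence = vapply(parsed, `[[`, character(1), "consequence"),
        c_dot = vapply(parsed, `[[`, character(1), "c_dot"),
        stringsAsFactors = FALSE)
    structure(list(variants = variants, dosages = dos,
                   samples = colnames(gt)), class = "seq_panel")
}

#' Read a plain-text variant annotation sidecar
#'
#' Alternative to SnpEff-annotated VCF input for synthetic data: a TSV
#' with columns `chrom pos ref alt gene transcript consequence c_dot`
#' plus one dosage column per panel sample (0/1/2, NA allowed).
#'
#' @param path TSV file path.
#' @return list(`variants`, `dosages`, `samples`), class `seq_panel`.
#' @export
read_variant_sidecar <- function(path) {
    if (!file.exists(path)) .stopf("sidecar file not found: %s", path)
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = NA)
    need <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
              "consequence", "c_dot")
    if (!all(need %in% names(tab)))
        .stopf("sidecar must have columns: %s", paste(need, collapse = " "))
    samples <- setdiff(names(tab), need)
    dos <- as.matrix(tab[, samples, drop = FALSE])
    storage.mode(dos) <- "integer"
    variants <- tab[, need, drop = FALSE]
    variants$chrom <- as.character(variants$chrom)
    structure(list(variants = variants, dosages = dos, samples = samples),
              class = "seq_panel")
}

#' Write the sidecar TSV for a sequenced panel
#'
#' @param panel a `seq_panel`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_sidecar <- function(panel, path) {
    stopifnot(inherits(panel, "seq_panel"))
    v <- panel$variants[c("chrom", "pos", "ref", "alt", "gene", "transcript",
                          "consequence", "c_dot")]
    out <- cbind(v, as.data.frame(panel$dosages))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
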