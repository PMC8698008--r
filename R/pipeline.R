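#' Load a pipeline configuration
#'
#' JSON file (or list) with optional sections `sim`, `qc`, `scan`, `link`
#' and top-level `out`, `seed`, `write_windows`; unknown keys are
#' rejected, missing ones take the package defaults. The `sim` section
#' accepts a `lethal_loci` array of [lethal_locus()] field sets.
#'
#' @param config path to a JSON file, or a list.
#' @return A `pipeline_config` list with materialized [sim_config()],
#'   [qc_thresholds()] and [scan_config()] objects.
#' @export
pipeline_config <- function(config = list()) {
    if (is.character(config)) {
        if (!file.exists(config)) .stopf("config file not found: %s", config)
        config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE)
    }
    stopifnot(is.list(config))
    known <- c("out", "seed", "write_windows", "sim", "qc", "scan", "link")
    extra <- setdiff(names(config), known)
    if (length(extra))
        .stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
    simargs <- config$sim %||% list()
    if (!is.null(simargs$lethal_loci))
        simargs$lethal_loci <- lapply(simargs$lethal_loci, function(l)
            do.call(lethal_locus, as.list(l)))
    if (!is.null(config$seed)) simargs$seed <- config$seed
    structure(list(
        out = config$out %||% "haplodeficit_run",
        seed = as.integer(config$seed %||% simargs$seed %||% 1L),
        write_windows = isTRUE(config$write_windows),
        sim = do.call(sim_config, simargs),
        qc = do.call(qc_thresholds, config$qc %||% list()),
        scan = do.call(scan_config, config$scan %||% list()),
        link = list(r2_threshold =
                        (config$link %||% list())$r2_threshold %||% 1.0,
                    tol = (config$link %||% list())$tol %||% 1e-9)),
        class = "pipeline_config")
}

#' Write a stage manifest
#'
#' Records tool version, seed, a hash of the effective configuration,
#' input file checksums and per-stage record counts, so a run can be
#' audited and reruns compared by checksum.
#' @noRd
.write_manifest <- function(out_dir, stage, cfg, inputs = character(0),
                            counts = list(), seed = NA) {
    man <- list(tool = "haplodeficit",
                version = as.character(packageVersion("haplodeficit")),
                stage = stage,
                seed = seed,
                config_md5 = .object_md5(cfg),
                inputs = lapply(inputs[file.exists(inputs)], function(f)
                    list(path = f, md5 = unname(tools::md5sum(f)))),
                counts = counts,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(man, file.path(out_dir,
                                        sprintf("manifest_%s.json", stage)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(man)
}

#' Pipeline stage: simulate and export a population
#'
#' Writes the simulated genotypes/pedigree/map/truth file set plus the
#' sequenced carrier panel (annotated VCF and sidecar TSV) and a
#' manifest.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param out_dir output directory; defaults to the config's `out`.
#' @return Named vector of written paths, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), out_dir = NULL) {
    cfg <- if (inherits(config, "pipeline_config")) config
           else pipeline_config(config)
    out_dir <- out_dir %||% cfg$out
    if (cfg$sim$markers_per_chromosome < cfg$scan$window_size)
        .stopf(paste0("markers_per_chromosome (%d) is below the scan ",
                      "window size (%d); no window would fit"),
               cfg$sim$markers_per_chromosome, cfg$scan$window_size)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pop <- simulate_population(cfg$sim)
    paths <- export_population(pop, out_dir)
    if (!is.null(pop$truth)) {
        panel <- attach_sequence_panel(pop)
        pv <- file.path(out_dir, "panel.vcf")
        ps <- file.path(out_dir, "panel_sidecar.tsv")
        write_panel_vcf(panel, pv)
        write_variant_sidecar(panel, ps)
        paths <- c(paths, panel_vcf = pv, panel_sidecar = ps)
    }
    .write_manifest(out_dir, "simulate", cfg, inputs = unname(paths),
                    counts = list(animals = nrow(pop$pedigree),
                                  genotyped = length(pop$haplotypes$ids),
                                  removed = length(pop$removed_ids),
                                  markers = nrow(pop$map)),
                    seed = cfg$seed)
    invisible(paths)
}

#' Pipeline stage: QC, cohorts, scan and region report
#'
#' Loads a phased VCF and pedigree, applies QC, phases by trio rules when
#' the input is unphased (with a second QC-documented pass over the
#' report), builds the trio/pgp cohorts, runs the scan in the configured
#' cohort mode and writes `qc_report.tsv`, `regions.tsv`, optional
#' `windows.tsv` and a manifest. An empty cohort in a requested mode is a
#' data error.
#'
#' @param config a [pipeline_config()].
#' @param vcf,pedigree_file input paths; default to the simulate stage's
#'   outputs under the config's `out` directory.
#' @param out_dir output directory.
#' @return The `scan_regions` data frame, invisibly.
#' @export
cmd_scan <- function(config = pipeline_config(), vcf = NULL,
                     pedigree_file = NULL, out_dir = NULL) {
    cfg <- if (inherits(config, "pipeline_config")) config
           else pipeline_config(config)
    out_dir <- out_dir %||% cfg$out
    vcf <- vcf %||% file.path(out_dir, "genotypes.vcf")
    pedigree_file <- pedigree_file %||% file.path(out_dir, "pedigree.tsv")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ds <- load_dataset(vcf, pedigree_file)
    qc <- qc_filter(ds$haplotypes, ds$map, cfg$qc)
    haps <- qc$haplotypes
    if (any(!haps$phased)) {
        haps <- trio_phase(haps, ds$pedigree)
        qc2 <- qc_filter(haps, qc$map, cfg$qc)
        haps <- qc2$haplotypes
        qc$map <- qc2$map
        qc$report <- rbind(qc$report, qc2$report)
    }
    write.table(qc$report, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cohorts <- build_cohorts(ds$pedigree, haps$ids)
    modes <- if (cfg$scan$cohort_mode == "both") c("trio", "pgp")
             else cfg$scan$cohort_mode
    for (mode in modes) {
        nn <- if (mode == "trio") nrow(cohorts$trios) else nrow(cohorts$pgp)
        if (!nn) .stopf("requested cohort mode '%s' has no groups", mode)
    }
    records <- scan(haps, qc$map, cohorts, cfg$scan)
    if (cfg$write_windows)
        write.table(records, file.path(out_dir, "windows.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    regions <- build_regions(records, qc$map, cfg$scan)
    write_region_report(regions, file.path(out_dir, "regions.tsv"))
    .write_manifest(out_dir, "scan", cfg,
                    inputs = c(vcf, pedigree_file),
                    counts = list(animals = length(haps$ids),
                                  markers = nrow(qc$map),
                                  trios = nrow(cohorts$trios),
                                  pgp = nrow(cohorts$pgp),
                                  tests = nrow(records),
                                  significant = sum(records$significant),
                                  regions = length(unique(regions$region_id))),
                    seed = cfg$seed)
    invisible(regions)
}

#' Read a regions.tsv written by [cmd_scan()]
#' @noRd
.read_region_report <- function(path) {
    if (!file.exists(path)) .stopf("region report not found: %s", path)
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = c(chrom = "character", hap = "character"))
}

#' Pipeline stage: link regions to candidate causal variants
#'
#' For every scanned region, computes diplotype dosages of the region's
#' top haplotype for the sequenced panel samples, screens the region's
#' protein-changing variants for linkage, and writes a candidate report
#' plus a per-variant LD table. The variant input must be an
#' ANN-annotated VCF (`panel.vcf`) or the sidecar TSV.
#'
#' @param config a [pipeline_config()].
#' @param regions_file,vcf,pedigree_file,panel_file input paths,
#'   defaulting to the earlier stages' outputs in `out_dir`.
#' @param out_dir output directory.
#' @return The combined `candidate_report`, invisibly.
#' @export
cmd_link <- function(config = pipeline_config(), regions_file = NULL,
                     vcf = NULL, pedigree_file = NULL, panel_file = NULL,
                     out_dir = NULL) {
    cfg <- if (inherits(config, "pipeline_config")) config
           else pipeline_config(config)
    out_dir <- out_dir %||% cfg$out
    regions_file <- regions_file %||% file.path(out_dir, "regions.tsv")
    vcf <- vcf %||% file.path(out_dir, "genotypes.vcf")
    pedigree_file <- pedigree_file %||% file.path(out_dir, "pedigree.tsv")
    if (is.null(panel_file)) {
        panel_file <- file.path(out_dir, "panel.vcf")
        if (!file.exists(panel_file))
            panel_file <- file.path(out_dir, "panel_sidecar.tsv")
    }
    if (!file.exists(panel_file))
        .stopf(paste0("no annotated panel found (%s); cmd_link requires an ",
                      "ANN-annotated VCF or a sidecar TSV"), panel_file)
    regions <- .read_region_report(regions_file)
    panel <- if (grepl("\\.vcf$", panel_file))
        read_annotated_variants(panel_file) else read_variant_sidecar(panel_file)
    ds <- load_dataset(vcf, pedigree_file)
    cands <- list()
    ld_rows <- list()
    for (i in seq_len(nrow(regions))) {
        rg <- regions[i, ]
        # regions.tsv stores the top window's bp bounds; marker indices in
        # the freshly loaded map are recomputed from them so the link stage
        # is robust to marker-index shifts from QC
        cols <- which(ds$map$chrom == rg$chrom &
                      ds$map$pos_bp >= rg$top_start_bp &
                      ds$map$pos_bp <= rg$top_end_bp)
        if (length(cols) != nchar(rg$hap))
            .stopf(paste0("region %s: top window spans %d markers in the ",
                          "loaded map but the haplotype has %d alleles"),
                   rg$region_id, length(cols), nchar(rg$hap))
        in_panel <- intersect(panel$samples, ds$haplotypes$ids)
        if (!length(in_panel))
            .stopf("no panel sample is present in the genotype matrix")
        dip <- diplotypes(ds$haplotypes,
                          list(start_idx = cols[1L],
                               end_idx = cols[length(cols)]),
                          rg$hap, in_panel)
        rep_i <- candidate_screen(
            list(region_id = rg$region_id, chrom = rg$chrom,
                 ext_start_bp = rg$ext_start_bp, ext_end_bp = rg$ext_end_bp),
            dip, panel$variants, panel$dosages,
            r2_threshold = cfg$link$r2_threshold, tol = cfg$link$tol)
        cands[[i]] <- rep_i
        all_i <- candidate_screen(
            list(region_id = rg$region_id, chrom = rg$chrom,
                 ext_start_bp = rg$ext_start_bp, ext_end_bp = rg$ext_end_bp),
            dip, panel$variants, panel$dosages, r2_threshold = 0,
            tol = cfg$link$tol)
        ld_rows[[i]] <- all_i
    }
    cand <- do.call(rbind, c(cands, list(make.row.names = FALSE)))
    ldt <- do.call(rbind, c(ld_rows, list(make.row.names = FALSE)))
    if (is.null(cand)) cand <- data.frame()
    if (is.null(ldt)) ldt <- data.frame()
    write.table(cand, file.path(out_dir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ldt, file.path(out_dir, "ld_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_manifest(out_dir, "link", cfg,
                    inputs = c(regions_file, vcf, pedigree_file, panel_file),
                    counts = list(regions = nrow(regions),
                                  candidates = nrow(cand)),
                    seed = cfg$seed)
    invisible(cand)
}

#' Run the full pipeline (simulate, scan, link) on one configuration
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list(`regions`, `candidates`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
    cfg <- if (inherits(config, "pipeline_config")) config
           else pipeline_config(config)
    out_dir <- out_dir %||% cfg$out
    cmd_simulate(cfg, out_dir)
    regions <- cmd_scan(cfg, out_dir = out_dir)
    cands <- NULL
    if (file.exists(file.path(out_dir, "panel.vcf")) && nrow(regions))
        cands <- cmd_link(cfg, out_dir = out_dir)
    invisible(list(regions = regions, candidates = cands))
}
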