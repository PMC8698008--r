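#' Configuration of the missing-homozygosity scan
#'
#' @param window_size window width in markers (default 50, the standard
#'   width for this kind of array-density screen).
#' @param step windows advance by this many markers (default 1: windows
#'   move marker by marker).
#' @param alpha significance level applied to the FDR-adjusted p-values.
#' @param min_haplotype_freq haplotypes below this frequency are not
#'   tested.
#' @param min_expected_homozygotes haplotypes whose expected homozygote
#'   count is below this are not tested (a deficit is undetectable there).
#' @param region_extension bp added on both sides of a merged significant
#'   interval (default 2 Mb).
#' @param cohort_mode `"trio"`, `"pgp"` or `"both"`; which analysis
#'   cohort(s) of offspring enter the test.
#' @param expected_mode `"hwe"` (expected homozygotes `n q^2` from the
#'   analyzed animals) or `"transmission"` (expectation from ancestor
#'   diplotypes; see [expected_homozygotes()]).
#' @param alternative test direction; the screen looks for a `"deficit"`.
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_size = 50L, step = 1L, alpha = 0.05,
                        min_haplotype_freq = 0.01,
                        min_expected_homozygotes = 1.0,
                        region_extension = 2e6,
                        cohort_mode = c("both", "trio", "pgp"),
                        expected_mode = c("hwe", "transmission"),
                        alternative = c("deficit", "two.sided")) {
    stopifnot(.is_count(window_size, 2L), .is_count(step, 1L),
              length(alpha) == 1L, alpha > 0, alpha < 1,
              .is_prob(min_haplotype_freq),
              length(min_expected_homozygotes) == 1L,
              min_expected_homozygotes >= 0,
              length(region_extension) == 1L, region_extension >= 0)
    structure(list(window_size = as.integer(window_size),
                   step = as.integer(step), alpha = alpha,
                   min_haplotype_freq = min_haplotype_freq,
                   min_expected_homozygotes = min_expected_homozygotes,
                   region_extension = region_extension,
                   cohort_mode = match.arg(cohort_mode),
                   expected_mode = match.arg(expected_mode),
                   alternative = match.arg(alternative)),
              class = "scan_config")
}

#' Enumerate scan windows over a marker map
#'
#' Windows never span chromosomes; a chromosome with fewer markers than
#' the window width is skipped with a warning. With step 1 a chromosome
#' of `M` markers yields `M - W + 1` windows.
#'
#' @param map a [marker_map()].
#' @param config a [scan_config()].
#' @return Data frame: `chrom`, `start_idx`/`end_idx` (row indices into
#'   `map`, inclusive), `start_bp`/`end_bp`.
#' @export
enumerate_windows <- function(map, config = scan_config()) {
    validate_marker_map(map)
    W <- config$window_size
    out <- lapply(unique(map$chrom), function(ch) {
        rows <- which(map$chrom == ch)
        if (length(rows) < W) {
            .warnf("chromosome %s has %d < %d markers; skipped",
                   ch, length(rows), W)
            return(NULL)
        }
        starts <- rows[seq(1L, length(rows) - W + 1L, by = config$step)]
        data.frame(chrom = ch, start_idx = starts, end_idx = starts + W - 1L,
                   start_bp = map$pos_bp[starts],
                   end_bp = map$pos_bp[starts + W - 1L],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Animal usability and working alleles for scanning
#'
#' Returns the cohort submatrix with phase-unusable information masked:
#' animals without phase information are dropped; sites whose phase was
#' left unresolved by [trio_phase()] are set missing so that windows
#' touching them are excluded for that animal.
#' @noRd
.scan_alleles <- function(matrix, animals) {
    ai <- match(animals, matrix$ids)
    if (anyNA(ai)) .stopf("cohort animal(s) missing from genotype matrix: %s",
                          paste(animals[is.na(ai)], collapse = ", "))
    usable <- matrix$phased[ai]
    ai <- ai[usable]
    al <- matrix$alleles[.animal_rows(ai), , drop = FALSE]
    if (!is.null(matrix$unresolved) && nrow(matrix$unresolved)) {
        pos <- match(matrix$unresolved[, 1L], ai)
        keep <- !is.na(pos)
        if (any(keep)) {
            a <- pos[keep]
            m <- matrix$unresolved[keep, 2L]
            al[cbind(2L * a - 1L, m)] <- NA_integer_
            al[cbind(2L * a, m)] <- NA_integer_
        }
    }
    list(alleles = al, ids = matrix$ids[ai], n_unphased = sum(!usable))
}

#' Haplotype frequencies within one marker window
#'
#' Tallies the phased haplotypes of the given animals across a window.
#' Haplotypes containing a missing allele are excluded from the counts
#' (the excluded-animal count is reported); frequencies are relative to
#' the complete haplotypes and sum to 1.
#'
#' @param matrix a [hap_matrix()].
#' @param window one row of [enumerate_windows()] (or any list with
#'   `start_idx`/`end_idx`).
#' @param animals character vector of animal ids (default: all).
#' @return list(`table` = data frame `hap`,`count`,`q` sorted by
#'   decreasing count, `n_complete`, `n_excluded`).
#' @export
window_haplotypes <- function(matrix, window, animals = matrix$ids) {
    sc <- .scan_alleles(matrix, animals)
    cols <- seq.int(window$start_idx, window$end_idx)
    al <- sc$alleles[, cols, drop = FALSE]
    n_anim <- nrow(al) %/% 2L
    complete_row <- rowSums(is.na(al)) == 0L
    complete <- complete_row[seq(1L, 2L * n_anim, 2L)] &
        complete_row[seq(2L, 2L * n_anim, 2L)]
    rows <- al[rep(complete, each = 2L), , drop = FALSE]
    n_complete <- sum(complete)
    if (!n_complete) {
        .warnf("window %d-%d: no complete haplotypes; skipped",
               window$start_idx, window$end_idx)
        return(list(table = data.frame(hap = character(0), count = integer(0),
                                       q = numeric(0)),
                    n_complete = 0L,
                    n_excluded = n_anim + sc$n_unphased))
    }
    h <- do.call(paste0, as.data.frame(rows))
    tab <- sort(table(h), decreasing = TRUE)
    out <- data.frame(hap = names(tab), count = as.integer(tab),
                      q = as.integer(tab) / (2 * n_complete),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    list(table = out, n_complete = n_complete,
         n_excluded = (n_anim - n_complete) + sc$n_unphased)
}

#' Diplotype dosage of a focal haplotype
#'
#' Number of an animal's two phased window haplotypes identical to the
#' focal allele string: 0, 1 or 2; `NA` for animals with missing window
#' data (and for unphased animals, which are excluded from scanning).
#'
#' @param matrix a [hap_matrix()].
#' @param window as in [window_haplotypes()].
#' @param focal allele string (`"0"`/`"1"` characters) of window width.
#' @param animals animal ids.
#' @return Named integer vector of dosages.
#' @export
diplotypes <- function(matrix, window, focal, animals = matrix$ids) {
    sc <- .scan_alleles(matrix, animals)
    cols <- seq.int(window$start_idx, window$end_idx)
    fv <- as.integer(strsplit(focal, "")[[1]])
    if (length(fv) != length(cols))
        .stopf("focal haplotype length %d != window width %d",
               length(fv), length(cols))
    d <- window_dosage_cpp(sc$alleles[, cols, drop = FALSE], fv)
    full <- rep(NA_integer_, length(animals))
    full[match(sc$ids, animals)] <- d
    setNames(full, animals)
}

#' Expected number of focal-haplotype homozygotes
#'
#' `mode = "hwe"`: the random-mating expectation `n q^2`. With the full
#' genotyped population (here n = 9965-style counts) this reproduces the
#' published expected-homozygote arithmetic of such screens.
#' `mode = "transmission"`: sums, over cohort offspring, the probability
#' of homozygosity given ancestor diplotype dosages: for a trio
#' `(d_sire/2) (d_dam/2)`; for a pgp group
#' `(d_sire/2) ((d_mgs/2)(1/2) + q/2)`, the maternal-granddam allele being
#' drawn at the population frequency `q`.
#'
#' @param n number of analyzed animals (hwe mode).
#' @param q focal haplotype frequency.
#' @param mode `"hwe"` or `"transmission"`.
#' @param trio_dosages data frame with columns `d_sire`, `d_dam` (one row
#'   per trio offspring; transmission mode).
#' @param pgp_dosages data frame with columns `d_sire`, `d_mgs` (one row
#'   per pgp offspring; transmission mode).
#' @return Expected homozygote count (not rounded).
#' @export
expected_homozygotes <- function(n, q, mode = c("hwe", "transmission"),
                                 trio_dosages = NULL, pgp_dosages = NULL) {
    mode <- match.arg(mode)
    if (!is.numeric(q) || any(q < 0 | q > 1)) .stopf("q must lie in [0, 1]")
    if (mode == "hwe") return(n * q^2)
    e <- 0
    if (!is.null(trio_dosages) && nrow(trio_dosages))
        e <- e + sum((trio_dosages$d_sire / 2) * (trio_dosages$d_dam / 2))
    if (!is.null(pgp_dosages) && nrow(pgp_dosages))
        e <- e + sum((pgp_dosages$d_sire / 2) *
                     ((pgp_dosages$d_mgs / 2) * 0.5 + q * 0.5))
    e
}

#' Exact tail probability of a sum of independent Bernoulli variables
#'
#' P(X <= obs) for X a Poisson-binomial sum; used for the transmission
#' expectation mode. Dynamic programme truncated at obs + 1 successes.
#' @noRd
.poisbinom_tail <- function(probs, obs) {
    probs <- probs[probs > 0]
    if (obs >= length(probs)) return(1)
    f <- c(1, numeric(obs))               # f[k+1] = P(X = k), k <= obs;
    for (p in probs)                      # mass beyond obs is dropped
        f <- f * (1 - p) + c(0, f[seq_len(obs)]) * p
    min(1, sum(f))
}

#' Genome-wide missing-homozygosity scan
#'
#' For every window and every haplotype passing the frequency and
#' expected-homozygote eligibility thresholds, counts observed focal
#' homozygotes among the cohort offspring, computes the expectation, the
#' percent deficiency `100 (E - O) / E`, the one-sided exact
#' Hardy-Weinberg deficit p-value, and Benjamini-Yekutieli-adjusted
#' p-values across all (window, haplotype) tests of the same cohort run.
#' With `cohort_mode = "both"`, the trio and pgp runs are performed and
#' adjusted separately and the records concatenated.
#'
#' @param matrix a phased, QC-passed [hap_matrix()].
#' @param map the aligned [marker_map()].
#' @param cohorts a [build_cohorts()] result.
#' @param config a [scan_config()].
#' @return A `hap_scan` data frame, one row per tested (window, haplotype):
#'   `approach chrom start_idx end_idx start_bp end_bp hap n q observed
#'   expected deficiency p p_adj significant`.
#' @export
scan <- function(matrix, map, cohorts, config = scan_config()) {
    stopifnot(inherits(matrix, "hap_matrix"), inherits(config, "scan_config"))
    validate_marker_map(map)
    modes <- if (config$cohort_mode == "both") c("trio", "pgp")
             else config$cohort_mode
    res <- lapply(modes, function(mode) {
        offs <- if (mode == "trio") cohorts$trios$offspring
                else cohorts$pgp$offspring
        offs <- unique(offs)
        if (!length(offs)) {
            .warnf("empty %s cohort; no tests run", mode)
            return(NULL)
        }
        rec <- .scan_one_cohort(matrix, map, offs, mode, cohorts, config)
        if (is.null(rec) || !nrow(rec)) return(NULL)
        rec$p_adj <- by_adjust(rec$p)
        rec$significant <- rec$p_adj < config$alpha
        rec
    })
    out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(approach = character(0), chrom = character(0),
                          start_idx = integer(0), end_idx = integer(0),
                          start_bp = numeric(0), end_bp = numeric(0),
                          hap = character(0), n = integer(0), q = numeric(0),
                          observed = integer(0), expected = numeric(0),
                          deficiency = numeric(0), p = numeric(0),
                          p_adj = numeric(0), significant = logical(0))
    class(out) <- c("hap_scan", "data.frame")
    attr(out, "config") <- config
    out
}

#' One cohort-mode scan pass
#' @noRd
.scan_one_cohort <- function(matrix, map, offs, mode, cohorts, config) {
    sc <- .scan_alleles(matrix, offs)
    if (!length(sc$ids)) return(NULL)
    W <- config$window_size
    chunks <- lapply(unique(map$chrom), function(ch) {
        cols <- which(map$chrom == ch)
        if (length(cols) < W) {
            .warnf("chromosome %s has %d < %d markers; skipped",
                   ch, length(cols), W)
            return(NULL)
        }
        al <- sc$alleles[, cols, drop = FALSE]
        t <- if (W <= 64L)
            scan_tally_cpp(al, W, config$min_haplotype_freq,
                           config$min_expected_homozygotes)
        else .scan_tally_r(al, W, config$min_haplotype_freq,
                           config$min_expected_homozygotes)
        if (!length(t$window)) return(NULL)
        keep <- ((t$window - 1L) %% config$step) == 0L
        s_global <- cols[t$window[keep]]
        data.frame(approach = mode, chrom = ch,
                   start_idx = s_global, end_idx = s_global + W - 1L,
                   start_bp = map$pos_bp[s_global],
                   end_bp = map$pos_bp[s_global + W - 1L],
                   hap = t$hap[keep], n = t$n_complete[keep],
                   q = t$count[keep] / (2 * t$n_complete[keep]),
                   observed = t$hom[keep],
                   count = t$count[keep],
                   stringsAsFactors = FALSE)
    })
    rec <- do.call(rbind, c(chunks, list(make.row.names = FALSE)))
    if (is.null(rec) || !nrow(rec)) return(NULL)
    if (config$expected_mode == "hwe") {
        rec$expected <- rec$n * rec$q^2
        n_AB <- rec$count - 2L * rec$observed
        if (config$alternative == "deficit") {
            rec$p <- .hwe_deficit_p_batch(rec$observed, rec$count, rec$n)
        } else {
            rec$p <- mapply(exact_hwe_deficit_test, rec$observed, n_AB,
                            rec$n - rec$observed - n_AB,
                            MoreArgs = list(alternative = "two.sided"))
        }
    } else {
        et <- .transmission_expectation(matrix, rec, mode, cohorts)
        rec$expected <- et$expected
        rec$p <- et$p
        keep <- rec$expected >= config$min_expected_homozygotes
        rec <- rec[keep, , drop = FALSE]
    }
    # parenthesized so a zero-observed haplotype gives exactly 100
    rec$deficiency <- ifelse(rec$expected > 0,
                             100 * ((rec$expected - rec$observed) /
                                        rec$expected), NA_real_)
    rec$count <- NULL
    rec
}

#' Transmission-mode expectation and Poisson-binomial deficit p-values
#' @noRd
.transmission_expectation <- function(matrix, rec, mode, cohorts) {
    expected <- numeric(nrow(rec))
    p <- numeric(nrow(rec))
    groups <- if (mode == "trio") cohorts$trios else cohorts$pgp
    for (i in seq_len(nrow(rec))) {
        win <- list(start_idx = rec$start_idx[i], end_idx = rec$end_idx[i])
        anc1 <- diplotypes(matrix, win, rec$hap[i], unique(groups$sire))
        if (mode == "trio") {
            anc2 <- diplotypes(matrix, win, rec$hap[i], unique(groups$dam))
            pr <- (anc1[groups$sire] / 2) * (anc2[groups$dam] / 2)
        } else {
            anc2 <- diplotypes(matrix, win, rec$hap[i], unique(groups$mgs))
            pr <- (anc1[groups$sire] / 2) *
                ((anc2[groups$mgs] / 2) * 0.5 + rec$q[i] * 0.5)
        }
        pr <- pr[!is.na(pr)]
        expected[i] <- sum(pr)
        p[i] <- .poisbinom_tail(pr, rec$observed[i])
    }
    list(expected = expected, p = p)
}

#' String-based window tally fallback for windows wider than 64 markers
#' @noRd
.scan_tally_r <- function(al, W, q_min, e_min) {
    M <- ncol(al)
    n_anim <- nrow(al) %/% 2L
    out <- list(window = integer(0), hap = character(0), count = integer(0),
                hom = integer(0), n_complete = integer(0))
    if (M < W || !n_anim) return(out)
    full <- do.call(paste0, as.data.frame(ifelse(is.na(al), "N", al)))
    for (s in seq_len(M - W + 1L)) {
        h <- substr(full, s, s + W - 1L)
        ok_row <- !grepl("N", h, fixed = TRUE)
        ok <- ok_row[seq(1L, 2L * n_anim, 2L)] & ok_row[seq(2L, 2L * n_anim, 2L)]
        n_c <- sum(ok)
        if (!n_c) next
        h1 <- h[seq(1L, 2L * n_anim, 2L)][ok]
        h2 <- h[seq(2L, 2L * n_anim, 2L)][ok]
        tab <- table(c(h1, h2))
        homs <- table(h1[h1 == h2])
        for (hap in names(tab)) {
            cnt <- as.integer(tab[[hap]])
            q <- cnt / (2 * n_c)
            if (q < q_min || n_c * q^2 < e_min) next
            out$window <- c(out$window, s)
            out$hap <- c(out$hap, hap)
            out$count <- c(out$count, cnt)
            out$hom <- c(out$hom,
                         if (hap %in% names(homs)) as.integer(homs[[hap]])
                         else 0L)
            out$n_complete <- c(out$n_complete, n_c)
        }
    }
    out
}
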