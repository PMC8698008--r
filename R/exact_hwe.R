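#' Exact conditional distribution of homozygote counts under Hardy-Weinberg
#'
#' Conditional on the sample size `n` (diploid individuals) and the focal
#' allele count `n_A`, random union of gametes gives the heterozygote count
#' `n_AB` a distribution with weights proportional to
#' \deqn{n! \, 2^{n_{AB}} / (n_{AA}!\, n_{AB}!\, n_{BB}!),}
#' where `n_AA = (n_A - n_AB)/2` and `n_BB = n - n_AA - n_AB`. This is the
#' distribution underlying the exact test of Hardy-Weinberg equilibrium;
#' only heterozygote counts with the parity of `n_A` are possible.
#'
#' @param n number of diploid individuals (> 0).
#' @param n_A count of the focal allele among the `2 n` alleles.
#' @return A data frame with columns `n_AA`, `n_AB`, `n_BB` and `prob`,
#'   one row per reachable genotype configuration, probabilities summing
#'   to 1.
#' @export
#' @examples
#' hwe_exact_dist(5, 4)
hwe_exact_dist <- function(n, n_A) {
    if (!.is_count(n, min = 1L)) .stopf("n must be a positive integer")
    if (!.is_count(n_A) || n_A > 2L * n)
        .stopf("n_A must be an integer in [0, 2n]")
    n_AB <- seq.int(n_A %% 2L, min(n_A, 2L * n - n_A), by = 2L)
    n_AA <- (n_A - n_AB) %/% 2L
    n_BB <- n - n_AA - n_AB
    lw <- lfactorial(n) + n_AB * log(2) -
        lfactorial(n_AA) - lfactorial(n_AB) - lfactorial(n_BB)
    pr <- exp(lw - .logsumexp(lw))
    data.frame(n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, prob = pr)
}

#' Exact test for a deficit of focal-haplotype homozygotes
#'
#' One-sided exact Hardy-Weinberg test conditioning on the observed focal
#' allele count: the p-value is the probability, over all genotype
#' configurations with the same sample size and allele count, of observing
#' at most (`"deficit"`, the default) the observed number of focal
#' homozygotes. `"excess"` and `"two.sided"` are available behind the
#' `alternative` flag. All weights are accumulated in log space, so large
#' counts do not overflow. The degenerate cases `n_A <= 1` (a single
#' reachable configuration) return p = 1.
#'
#' @param n_AA observed homozygotes for the focal haplotype.
#' @param n_AB observed heterozygotes (focal with any other haplotype).
#' @param n_BB observed animals without a copy of the focal haplotype.
#' @param alternative `"deficit"` (default), `"excess"` or `"two.sided"`.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' exact_hwe_deficit_test(0, 4, 1)  # 80/210
exact_hwe_deficit_test <- function(n_AA, n_AB, n_BB,
                                   alternative = c("deficit", "excess",
                                                   "two.sided")) {
    alternative <- match.arg(alternative)
    for (v in list(n_AA, n_AB, n_BB))
        if (!.is_count(v)) .stopf("genotype counts must be non-negative integers")
    n <- n_AA + n_AB + n_BB
    if (n == 0L) .stopf("at least one individual is required")
    d <- hwe_exact_dist(n, 2L * n_AA + n_AB)
    switch(alternative,
        deficit = sum(d$prob[d$n_AA <= n_AA]),
        excess = sum(d$prob[d$n_AA >= n_AA]),
        two.sided = {
            p_obs <- d$prob[d$n_AA == n_AA]
            min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-7)]))
        })
}

#' Deficit p-values for many (n, n_A, n_AA) records, with caching
#'
#' Used by [scan()]: across thousands of windows the same conditional
#' distribution recurs constantly, so distributions are computed once per
#' unique (n, n_A) pair.
#' @noRd
.hwe_deficit_p_batch <- function(n_AA, n_A, n) {
    stopifnot(length(n_AA) == length(n_A), length(n) == length(n_A))
    p <- numeric(length(n_AA))
    key <- paste(n, n_A, sep = ":")
    for (k in unique(key)) {
        idx <- which(key == k)
        d <- hwe_exact_dist(n[idx[1L]], n_A[idx[1L]])
        # support is ordered by decreasing n_AA: P(X <= obs) is the tail
        # sum from the matched row on, accumulated from the small end so
        # tiny p-values keep full relative precision
        tail_sum <- rev(cumsum(rev(d$prob)))
        pos <- match(n_AA[idx], d$n_AA)
        if (anyNA(pos)) .stopf("internal error: homozygote count off support")
        p[idx] <- pmin(tail_sum[pos], 1)
    }
    p
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence: the raw
#' p-values are inflated by `m * c(m) / rank` with the harmonic factor
#' `c(m) = sum_{k=1..m} 1/k`, then made monotone from the largest rank
#' down and capped at 1. Order of the input is preserved.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' by_adjust(c(0.01, 0.02, 0.9))  # 0.055 0.055 1
by_adjust <- function(pvals) {
    if (length(pvals) == 0L) return(numeric(0))
    if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
        .stopf("p-values must lie in (0, 1]")
    m <- length(pvals)
    cm <- sum(1 / seq_len(m))
    o <- order(pvals, decreasing = TRUE)
    ranks <- m:1L
    adj <- pmin(1, cummin(m * cm * pvals[o] / ranks))
    out <- numeric(m)
    out[o] <- adj
    out
}
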