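# Independent oracles for the exact HWE deficit test. Both avoid the
# log-factorial path used by the implementation.

# Brute force over all ordered gamete assignments (4^n states); exact for
# small n. Returns P(n_AA = 0..n) conditional on the focal allele count.
enum_hwe_dist <- function(n, n_A) {
    states <- as.matrix(expand.grid(rep(list(0:3), n)))  # 0:00 1:01 2:10 3:11
    acount <- rowSums(states == 1L) + rowSums(states == 2L) +
        2L * rowSums(states == 3L)
    keep <- states[acount == n_A, , drop = FALSE]
    hom <- rowSums(keep == 3L)
    tab <- table(factor(hom, levels = 0:n))
    as.numeric(tab) / nrow(keep)
}

# Enumeration over all genotype configurations via the exact weight-ratio
# recurrence: converting one homozygote + one non-carrier into two
# heterozygotes multiplies the configuration weight by
# 4 a b / ((h+1)(h+2)). Support ordered by increasing heterozygote count
# (decreasing n_AA), matching hwe_exact_dist().
ratio_hwe_dist <- function(n, n_A) {
    h <- seq.int(n_A %% 2L, min(n_A, 2L * n - n_A), by = 2L)
    w <- numeric(length(h))
    w[1] <- 1
    for (i in seq_along(h)[-1]) {
        hh <- h[i - 1L]
        a <- (n_A - hh) / 2
        b <- n - a - hh
        w[i] <- w[i - 1L] * 4 * a * b / ((hh + 1) * (hh + 2))
    }
    w / sum(w)
}
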