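#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions given the
#' allele counts. The p-value sums, over every heterozygote count
#' compatible with the observed allele counts, the conditional
#' probabilities that do not exceed the probability of the observed
#' configuration. For pair-level quality control the test is applied to
#' control genotypes only and a variant is kept when `p > 0.01`.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative
#'   integers, total >= 1).
#' @return the exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_alt <- 2 * n_hom_alt + n_het
  # heterozygote counts sharing the allele counts: same parity as n_alt,
  # bounded by both allele totals
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_alt - h) / 2
    nrr <- n - h - naa
    lfactorial(n) - lfactorial(nrr) - lfactorial(h) - lfactorial(naa) +
      h * log(2) +
      lfactorial(n_alt) + lfactorial(2 * n - n_alt) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
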