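# Direct-formula oracle for the Hardy-Weinberg exact test: enumerate all
# feasible heterozygote counts and evaluate the conditional probability with
# log-factorials (independent of the recurrence used by the implementation).
hweOracle <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  na <- 2 * n_hom_minor + n_het
  nb <- 2 * n - na
  hets <- seq(na %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(na) - lfactorial(nb))
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-12)])
}
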