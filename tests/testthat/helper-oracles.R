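# Independent brute-force references. These deliberately avoid the
# package's evaluation paths (no factorization, no series, no log-domain
# tricks) so they can serve as oracles for them.

# kernel straight from its defining closed form
oracle_kernel <- function(x, y, lambda) {
  lambda^length(x) * ((1 - lambda) / lambda)^sum(x != y)
}

# Parzen estimate as a literal mean of kernel values
oracle_density <- function(x, prototypes, lambda) {
  mean(apply(prototypes, 1L, function(p) oracle_kernel(x, p, lambda)))
}

# all 2^L binary vectors, one per row
enumerate_bits <- function(L) {
  E <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  dimnames(E) <- NULL
  storage.mode(E) <- "numeric"
  E
}

random_bits <- function(n, L, p = 0.5) {
  matrix(stats::rbinom(n * L, 1L, p), n, L)
}

# relative discrepancy of two log-scale densities
rel_err_log <- function(la, lb) abs(exp(la - lb) - 1)
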