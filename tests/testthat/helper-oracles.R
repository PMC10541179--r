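# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they stay independent of the package's
# implementations.

# Benjamini-Hochberg adjusted values by the step-up definition, O(m^2):
# the adjusted p of the hypothesis ranked i is min over j >= i of
# m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- numeric(0)
    for (j in i:m) cand <- c(cand, m * p[ord[j]] / j)
    q[ord[i]] <- min(c(cand, 1))
  }
  q
}

# canonical diffusion parameter set used in several tests
canonical_params <- function() list(v = 0.1, a = 0.14, ter = 0.30, s = 0.1)

# random valid diffusion parameters
random_params <- function(n) {
  lapply(seq_len(n), function(i)
    list(v = runif(1, -0.4, 0.4) + ifelse(runif(1) < 0.5, 0.05, -0.05),
         a = runif(1, 0.05, 0.2),
         ter = runif(1, 0.15, 0.5),
         s = 0.1))
}

# all length-<=6 combinations (with repetition) from a p-value pool
pvec_grid <- function(pool, max_len = 6) {
  out <- list()
  for (len in 1:max_len) {
    combs <- utils::combn(length(pool) + len - 1, len)
    # stars-and-bars: map combinations to multisets of pool indices
    for (k in seq_len(ncol(combs)))
      out[[length(out) + 1L]] <- pool[combs[, k] - seq_len(len) + 1]
  }
  out
}
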