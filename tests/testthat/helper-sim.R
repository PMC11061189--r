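# Small shared simulation setups used across test files.

small_pool_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_samples_per_pool = 3, n_nuclei_per_sample = 150,
         n_genes = 60, n_snps = 30, snp_depth_mean = 2,
         hto_signal_mean = 200, hto_background_mean = 5,
         hto_stain_efficiency = 1.0, doublet_rate = 0.05, seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

# tie-corrected two-proportion z-test with the exact permutation
# (finite-population, n - 1) variance — the oracle the binary rank-sum
# test must coincide with
prop_ztest_p <- function(x1, n1, x2, n2) {
  n <- n1 + n2
  p1 <- x1 / n1
  p2 <- x2 / n2
  p <- (x1 + x2) / n
  if (p == 0 || p == 1) return(1)
  z <- (p1 - p2) /
    sqrt(p * (1 - p) * (n / (n - 1)) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(z))
}

# brute-force posterior over all demux hypotheses for one cell
brute_force_posterior <- function(ad, dp, genotypes, eps, delta) {
  K <- nrow(genotypes)
  hyp <- list()
  prior <- c()
  for (k in seq_len(K)) {
    hyp[[length(hyp) + 1]] <- genotypes[k, ]
    prior <- c(prior, (1 - delta) / K)
  }
  pairs <- utils::combn(K, 2)
  for (c in seq_len(ncol(pairs))) {
    hyp[[length(hyp) + 1]] <-
      (genotypes[pairs[1, c], ] + genotypes[pairs[2, c], ]) / 2
    prior <- c(prior, delta / ncol(pairs))
  }
  lik <- vapply(hyp, function(g) {
    mu <- eps + (1 - 2 * eps) * g
    keep <- dp > 0
    prod(stats::dbinom(ad[keep], dp[keep], mu[keep]))
  }, numeric(1))
  w <- prior * lik
  w / sum(w)
}
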