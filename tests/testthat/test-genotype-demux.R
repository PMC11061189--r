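test_that("filter_variants enforces all three inclusive rules", {
  # six records spanning the rule combinations
  recs <- data.frame(
    snp = paste0("v", 1:6),
    depth = c(9, 100, 10, 100, 100, 4),
    alt = c(5, 5, 5, 4, 50, 4)
  )
  # truth table: depth>=10 & af>=0.05 & alt>=5
  kept <- filter_variants(recs)
  expect_setequal(kept$snp, c("v2", "v3", "v5"))
  # boundary: depth 9 fails depth rule even with af .56
  expect_false("v1" %in% kept$snp)
  # boundary inclusive: depth 100, alt 5, af exactly 0.05 kept
  expect_true("v2" %in% kept$snp)
  # alt 4 fails the alternate-depth rule despite af 0.04 < 0.05 too
  expect_false("v4" %in% kept$snp)
})

test_that("singlet_loglik matches term-by-term binomial arithmetic", {
  # dosages (1, 0, 0.5), eps = 0.01, alt/depth = (2/2, 0/2, 1/2)
  ll <- singlet_loglik(ad = c(2, 0, 1), dp = c(2, 2, 2),
                       dosage = c(1, 0, 0.5), eps = 0.01)
  expect_equal(as.numeric(ll), 4 * log(0.99) + log(0.5), tolerance = 1e-12)
  expect_equal(as.numeric(ll), -0.7333486, tolerance = 1e-6)

  # perfect-match homozygous data at eps -> 0 approaches loglik 0
  ll0 <- singlet_loglik(ad = c(3, 0), dp = c(3, 3), dosage = c(1, 0),
                        eps = 1e-12)
  expect_equal(as.numeric(ll0), 0, tolerance = 1e-10)

  # no covered SNPs returns 0 with the coverage flag
  llna <- singlet_loglik(ad = c(0, 0), dp = c(0, 0), dosage = c(1, 0))
  expect_equal(as.numeric(llna), 0)
  expect_equal(attr(llna, "n_covered"), 0L)

  # mismatches at homozygous sites make the true donor the argmax
  geno <- rbind(d1 = c(1, 1, 0, 0), d2 = c(0, 0, 1, 1), d3 = c(0.5, 1, 0, 1))
  ad <- c(3, 2, 0, 0); dp <- c(3, 2, 2, 3)  # generated by d1
  lls <- apply(geno, 1, function(g) as.numeric(
    singlet_loglik(ad, dp, g, eps = 0.01)))
  expect_identical(names(which.max(lls)), "d1")
  # brute-force check of each term
  for (d in rownames(geno)) {
    mu <- 0.01 + 0.98 * geno[d, ]
    expect_equal(unname(lls[d]), sum(dbinom(ad, dp, mu, log = TRUE)))
  }
})

test_that("doublet_loglik uses the mean dosage and is symmetric", {
  ad <- c(1, 2, 0); dp <- c(2, 4, 2)
  gi <- c(1, 1, 0); gj <- c(0, 1, 0)
  expect_equal(doublet_loglik(ad, dp, gi, gj),
               doublet_loglik(ad, dp, gj, gi))
  # degenerate pair equals the singlet likelihood
  expect_equal(as.numeric(doublet_loglik(ad, dp, gi, gi)),
               as.numeric(singlet_loglik(ad, dp, gi)))
  # half-alt data at depth 4 over 20 SNPs: doublet of opposite homozygotes
  # beats both singlets (brute-force likelihood table)
  g1 <- rep(1, 20); g0 <- rep(0, 20)
  adx <- rep(2, 20); dpx <- rep(4, 20)
  ll_dbl <- as.numeric(doublet_loglik(adx, dpx, g1, g0, eps = 0.01))
  ll_s1 <- as.numeric(singlet_loglik(adx, dpx, g1, eps = 0.01))
  ll_s0 <- as.numeric(singlet_loglik(adx, dpx, g0, eps = 0.01))
  expect_gt(ll_dbl, ll_s1)
  expect_gt(ll_dbl, ll_s0)
  expect_equal(ll_dbl, sum(dbinom(2, 4, 0.5, log = TRUE) * 20))
})

test_that("assign_genotype posteriors match brute-force enumeration", {
  geno <- rbind(S1 = c(1, 0, 0.5, 1), S2 = c(0, 1, 0.5, 0),
                S3 = c(0.5, 0.5, 1, 0))
  colnames(geno) <- paste0("SNP", 1:4)
  ad <- Matrix::Matrix(rbind(c(2, 0, 1), c(0, 1, 1), c(1, 2, 2), c(2, 0, 0)),
                       sparse = TRUE)
  dp <- Matrix::Matrix(rbind(c(2, 1, 2), c(1, 2, 2), c(2, 2, 2), c(2, 1, 1)),
                       sparse = TRUE)
  dimnames(ad) <- dimnames(dp) <- list(paste0("SNP", 1:4), paste0("c", 1:3))
  eps <- 0.01; delta <- 0.05
  calls <- assign_genotype(list(ad = ad, dp = dp), geno, eps = eps,
                           delta = delta, tau = 0.9)
  post <- attr(calls, "posterior_matrix")
  for (j in 1:3) {
    bf <- brute_force_posterior(as.matrix(ad)[, j], as.matrix(dp)[, j],
                                geno, eps, delta)
    expect_equal(unname(post[, j]), unname(bf), tolerance = 1e-10)
  }
  # posterior normalization
  expect_equal(unname(Matrix::colSums(post)), rep(1, 3), tolerance = 1e-12)

  # 2-donor 1-SNP toy with full hand table
  g2 <- rbind(A = 1, B = 0); colnames(g2) <- "SNP1"
  ad2 <- Matrix::Matrix(matrix(2, 1, 1), sparse = TRUE)
  dp2 <- Matrix::Matrix(matrix(2, 1, 1), sparse = TRUE)
  dimnames(ad2) <- dimnames(dp2) <- list("SNP1", "c1")
  calls2 <- assign_genotype(list(ad = ad2, dp = dp2), g2, eps = 0.01,
                            delta = 0.1, tau = 0.5)
  lik <- c(0.99^2, 0.01^2, 0.5^2)
  prior <- c(0.45, 0.45, 0.1)
  expect_equal(unname(attr(calls2, "posterior_matrix")[, 1]),
               prior * lik / sum(prior * lik), tolerance = 1e-12)
})

test_that("cells without coverage are UNASSIGNED with uniform posterior", {
  geno <- rbind(S1 = c(1, 0), S2 = c(0, 1))
  colnames(geno) <- paste0("SNP", 1:2)
  ad <- Matrix::Matrix(matrix(0, 2, 2), sparse = TRUE)
  dp <- Matrix::Matrix(cbind(c(2, 2), c(0, 0)), sparse = TRUE)
  ad[1, 1] <- 2
  dimnames(ad) <- dimnames(dp) <- list(paste0("SNP", 1:2), c("c1", "c2"))
  calls <- assign_genotype(list(ad = ad, dp = dp), geno, tau = 0.9)
  expect_identical(calls$label[2], "UNASSIGNED")
  expect_equal(unname(attr(calls, "posterior_matrix")[, 2]), rep(1 / 3, 3))
})

test_that("genotype demux recovers truth on a sparse-coverage pool", {
  cfg <- sim_config(n_samples_per_pool = 4, n_nuclei_per_sample = 1000,
                    n_snps = 50, snp_depth_mean = 2, allele_error = 0.01,
                    doublet_rate = 0.05, n_genes = 20, seed = 19)
  sim <- simulate_pool(cfg)
  calls <- assign_genotype(sim$dataset$allele, sim$dataset$genotypes,
                           eps = 0.01, delta = 0.05, tau = 0.9)
  tr <- sim$truth
  sing <- !tr$doublet
  assigned <- !(calls$label %in% c("DOUBLET", "UNASSIGNED"))
  acc <- mean(calls$label[sing & assigned] == tr$sample1[sing & assigned])
  expect_gte(acc, 0.95)
  expect_gte(mean(calls$label[tr$doublet] == "DOUBLET"), 0.5)
})

test_that("assignment accuracy grows with SNP depth", {
  acc_at <- function(depth) {
    cfg <- sim_config(n_samples_per_pool = 3, n_nuclei_per_sample = 200,
                      n_snps = 20, snp_depth_mean = depth,
                      doublet_rate = 0, n_genes = 10, n_mito_genes = 0,
                      seed = 23)
    sim <- simulate_pool(cfg)
    calls <- assign_genotype(sim$dataset$allele, sim$dataset$genotypes)
    mean(calls$label == sim$truth$sample1)
  }
  a <- vapply(c(0.2, 1, 4), acc_at, numeric(1))
  expect_true(all(diff(a) > 0))
  expect_gt(a[3], 0.99)
})
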