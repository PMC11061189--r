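test_that("genotype simulation gives distinct donors and is seed-deterministic", {
  cfg <- sim_config(n_samples_per_pool = 4, n_snps = 50, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% c(0, 0.5, 1)))
  for (i in 1:3) {
    for (j in (i + 1):4) expect_true(any(g1[i, ] != g1[j, ]))
  }
  # 2 donors, 1 SNP: forced distinct at the single site
  g <- simulate_genotypes(sim_config(n_samples_per_pool = 2, n_snps = 1))
  expect_true(g[1, 1] != g[2, 1])
  # too few SNPs to distinguish donors is a configuration error
  expect_error(simulate_genotypes(sim_config(n_samples_per_pool = 10,
                                             n_snps = 1)),
               "configuration error")
})

test_that("simulated dosage frequencies match the uniform draw", {
  g <- simulate_genotypes(sim_config(n_samples_per_pool = 3, n_snps = 3000,
                                     seed = 21))
  obs <- table(factor(g, levels = c(0, 0.5, 1)))
  n <- length(g)
  # each dosage class within 4 SDs of the multinomial expectation n/3
  sd_cnt <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(obs - n / 3) < 4 * sd_cnt))
})

test_that("pool simulation respects configured truth structure", {
  cfg <- small_pool_config(seed = 3)
  sim <- simulate_pool(cfg)
  sim2 <- simulate_pool(cfg)
  expect_identical(sim, sim2)  # seed determinism

  tr <- sim$truth
  n <- nrow(tr)
  # every barcode appears exactly once in the truth and in the matrices
  expect_identical(sort(tr$barcode), sort(colnames(sim$dataset$counts)))
  expect_false(any(duplicated(tr$barcode)))
  expect_identical(colnames(sim$dataset$hto), tr$barcode)

  # doublet fraction within 3 binomial SDs of the configured rate
  d <- cfg$doublet_rate
  expect_lt(abs(mean(tr$doublet) - d), 3 * sqrt(d * (1 - d) / n) + 1e-12)

  # zero doublet rate produces zero doublets
  sim0 <- simulate_pool(small_pool_config(seed = 4, doublet_rate = 0))
  expect_equal(sum(sim0$truth$doublet), 0)
})

test_that("allele counts follow the binomial error model", {
  # with zero-ish error, homozygous-alt SNPs give only alt reads
  cfg <- small_pool_config(seed = 5, allele_error = 1e-12, doublet_rate = 0)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_pool(cfg, geno)
  ad <- as.matrix(sim$dataset$allele$ad)
  dp <- as.matrix(sim$dataset$allele$dp)
  for (s in cfg$samples) {
    cells <- sim$truth$barcode[sim$truth$sample1 == s]
    hom_alt <- names(which(geno[s, ] == 1))
    if (length(hom_alt) > 0 && length(cells) > 0) {
      expect_equal(ad[hom_alt, cells], dp[hom_alt, cells])
    }
    hom_ref <- names(which(geno[s, ] == 0))
    if (length(hom_ref) > 0 && length(cells) > 0) {
      expect_true(all(ad[hom_ref, cells] == 0))
    }
  }

  # mean alt fraction at het sites is 0.5 within 3 SEs (binomial oracle)
  cfg2 <- sim_config(n_samples_per_pool = 2, n_nuclei_per_sample = 2500,
                     n_genes = 20, n_snps = 40, snp_depth_mean = 3,
                     allele_error = 1e-12, doublet_rate = 0, seed = 6)
  geno2 <- simulate_genotypes(cfg2)
  sim2 <- simulate_pool(cfg2, geno2)
  ad2 <- as.matrix(sim2$dataset$allele$ad)
  dp2 <- as.matrix(sim2$dataset$allele$dp)
  fracs <- c()
  tot_reads <- 0
  for (s in cfg2$samples) {
    cells <- sim2$truth$barcode[sim2$truth$sample1 == s]
    het <- names(which(geno2[s, ] == 0.5))
    a <- sum(ad2[het, cells]); t <- sum(dp2[het, cells])
    fracs <- c(fracs, a); tot_reads <- tot_reads + t
  }
  frac <- sum(fracs) / tot_reads
  se <- sqrt(0.25 / tot_reads)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("HTO and depth means track the configuration at large n", {
  cfg <- sim_config(n_samples_per_pool = 2, n_nuclei_per_sample = 5000,
                    n_genes = 10, n_mito_genes = 0, n_snps = 20, snp_depth_mean = 2,
                    hto_signal_mean = 100, hto_background_mean = 4,
                    hto_stain_efficiency = 1.0, doublet_rate = 0, seed = 8)
  sim <- simulate_pool(cfg)
  hto <- sim$dataset$hto
  tag_of <- setNames(names(sim$dataset$tag_map), sim$dataset$tag_map)
  sig <- bg <- c()
  for (s in cfg$samples) {
    cells <- sim$truth$barcode[sim$truth$sample1 == s]
    own <- tag_of[s]
    sig <- c(sig, hto[own, cells])
    bg <- c(bg, hto[setdiff(rownames(hto), own), cells])
  }
  # NB variance mu + phi mu^2; 3-SE bands around configured means
  se_sig <- sqrt((100 + 0.5 * 100^2) / length(sig))
  se_bg <- sqrt((4 + 0.5 * 4^2) / length(bg))
  expect_lt(abs(mean(sig) - 100), 3 * se_sig)
  expect_lt(abs(mean(bg) - 4), 3 * se_bg)

  dp <- as.matrix(sim$dataset$allele$dp)
  expect_lt(abs(mean(dp) - 2), 3 * sqrt(2 / length(dp)))
})

test_that("confounded-expression generator produces the mixture-mean artifact", {
  sim <- simulate_confounded_expression(confounded_config(seed = 13))
  # null genes: marginal fold change approximates the mixture arithmetic
  # (0.8*10 + 0.2*1) / (0.2*10 + 0.8*1) = 2.9286
  conf <- sim$genes$gene[sim$genes$class == "confounded_null"]
  counts <- as.matrix(sim$counts[conf, , drop = FALSE])
  tum <- sim$cells$group == "tumor"
  fc <- mean(rowMeans(counts[, tum]) / rowMeans(counts[, !tum]))
  expect_lt(abs(fc - 8.2 / 2.8), 0.25)

  # identical compositions: no marginal difference in expectation
  simeq <- simulate_confounded_expression(confounded_config(
    composition_by_group = list(tumor = c(0.5, 0.5), nontumor = c(0.5, 0.5)),
    seed = 14))
  counts2 <- as.matrix(simeq$counts[
    simeq$genes$gene[simeq$genes$class == "confounded_null"], ])
  tum2 <- simeq$cells$group == "tumor"
  fc2 <- mean(rowMeans(counts2[, tum2]) / rowMeans(counts2[, !tum2]))
  expect_lt(abs(fc2 - 1), 0.25)

  # seeded rerun reproducible
  expect_identical(sim, simulate_confounded_expression(confounded_config(seed = 13)))
})

test_that("mitochondrial count fraction tracks the configured value", {
  cfg <- sim_config(n_samples_per_pool = 2, n_nuclei_per_sample = 1000,
                    n_genes = 100, mito_fraction = 0.04, seed = 15)
  sim <- simulate_pool(cfg)
  m <- sum(sim$dataset$counts[cfg$mito_genes, ]) / sum(sim$dataset$counts)
  expect_lt(abs(m - 0.04), 0.01)
})

test_that("dataset round-trips through the on-disk formats", {
  sim <- simulate_pool(small_pool_config(seed = 16, n_nuclei_per_sample = 40))
  dir <- tempfile("pool")
  write_pool_dataset(sim, dir)
  back <- read_pool_dataset(dir)
  expect_equal(as.matrix(back$dataset$counts), as.matrix(sim$dataset$counts))
  expect_equal(back$dataset$hto, sim$dataset$hto)
  expect_equal(as.matrix(back$dataset$allele$dp),
               as.matrix(sim$dataset$allele$dp))
  expect_equal(as.matrix(back$dataset$allele$ad),
               as.matrix(sim$dataset$allele$ad))
  expect_equal(back$dataset$genotypes, sim$dataset$genotypes)
  expect_equal(back$truth$sample1, sim$truth$sample1)
})
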