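test_that("quasi-Poisson point estimate matches the Poisson closed form", {
  set.seed(71)
  y <- c(rpois(300, 2), rpois(300, 4))
  grp <- factor(rep(c("nontumor", "tumor"), each = 300),
                levels = c("nontumor", "tumor"))
  f <- fit_gene_glm(y, grp)
  closed <- log(mean(y[301:600]) / mean(y[1:300]))
  expect_equal(f$estimate, closed, tolerance = 1e-8)
  expect_true(f$converged)

  # identical group means: estimate near 0, p not small
  set.seed(72)
  y0 <- rpois(600, 3)
  f0 <- fit_gene_glm(y0, grp)
  expect_lt(abs(f0$estimate), 0.15)
  expect_gt(f0$p, 0.05)
})

test_that("quasi-Poisson matches a reference GLM in the Poisson limit", {
  set.seed(73)
  y <- rpois(200, exp(1 + 0.5 * rep(c(0, 1), each = 100)))
  grp <- factor(rep(c("nontumor", "tumor"), each = 100),
                levels = c("nontumor", "tumor"))
  off <- rnorm(200, 0, 0.2)
  f <- fit_gene_glm(y, grp, offset = off)
  ref <- stats::glm(y ~ grp, family = quasipoisson(), offset = off)
  s <- summary(ref)$coefficients["grptumor", ]
  expect_equal(f$estimate, unname(s["Estimate"]), tolerance = 1e-6)
  expect_equal(f$se, unname(s["Std. Error"]), tolerance = 1e-6)
  expect_equal(f$p, unname(s["Pr(>|t|)"]), tolerance = 1e-6)
})

test_that("offsets make estimates invariant to depth rescaling", {
  set.seed(74)
  y <- rpois(200, 5)
  grp <- factor(rep(c("nontumor", "tumor"), each = 100),
                levels = c("nontumor", "tumor"))
  f1 <- fit_gene_glm(y, grp, offset = rep(0, 200))
  f2 <- fit_gene_glm(y * 2, grp, offset = rep(log(2), 200))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-4)
})

test_that("quasi-Poisson keeps type-I error while plain Poisson inflates it", {
  set.seed(75)
  n <- 200
  grp <- factor(rep(c("nontumor", "tumor"), each = n / 2),
                levels = c("nontumor", "tumor"))
  n_genes <- 400
  p_quasi <- p_pois <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    y <- rnbinom(n, size = 1, mu = 3)  # dispersion 1, no group effect
    f <- fit_gene_glm(y, grp)
    p_quasi[g] <- f$p
    fit <- suppressWarnings(stats::glm(y ~ grp, family = poisson()))
    p_pois[g] <- summary(fit)$coefficients["grptumor", "Pr(>|z|)"]
  }
  expect_gte(mean(p_quasi < 0.05), 0.02)
  expect_lte(mean(p_quasi < 0.05), 0.08)
  expect_gt(mean(p_pois < 0.05), 0.10)
})

test_that("run_de separates tumor types, BH within family", {
  sim <- simulate_confounded_expression(confounded_config(
    n_cells_per_group = 300, n_effect_genes = 20, n_confounded_genes = 20,
    n_background_genes = 20, seed = 76))
  de <- run_de(sim$counts, sim$cells$group, sim$cells$celltype,
               adjust = TRUE, referent = "nontumor",
               size_factors = sim$size_factors)
  expect_setequal(unique(de$tumor_type), "tumor")
  expect_equal(nrow(de), nrow(sim$genes))
  expect_identical(de$direction, ifelse(de$estimate >= 0, "up", "down"))
  expect_identical(de$significant, de$padj < 0.05)
  # effect genes dominate the significant set
  eff <- sim$genes$gene[sim$genes$class == "effect"]
  expect_gt(mean(de$significant[de$gene %in% eff]), 0.8)
})

test_that("cell-type adjustment removes composition confounding", {
  sim <- simulate_confounded_expression(confounded_config(
    n_cells_per_group = 500, n_effect_genes = 30, n_confounded_genes = 30,
    n_background_genes = 30, seed = 77))
  adj <- run_de(sim$counts, sim$cells$group, sim$cells$celltype,
                adjust = TRUE, size_factors = sim$size_factors)
  unadj <- run_de(sim$counts, sim$cells$group, adjust = FALSE,
                  size_factors = sim$size_factors)
  conf <- sim$genes$gene[sim$genes$class == "confounded_null"]
  rate_unadj <- mean(unadj$significant[unadj$gene %in% conf])
  rate_adj <- mean(adj$significant[adj$gene %in% conf])
  expect_gte(rate_unadj, 5 * max(rate_adj, 0.02))

  cmp <- compare_models(adj, unadj)
  expect_true(all(conf[unadj$significant[match(conf, unadj$gene)] &
                         !adj$significant[match(conf, adj$gene)]]
                  %in% cmp$tumor$unadjusted_only))
  # partition sanity: the three sets are disjoint
  expect_length(intersect(cmp$tumor$both, cmp$tumor$adjusted_only), 0)
  expect_length(intersect(cmp$tumor$both, cmp$tumor$unadjusted_only), 0)
})

test_that("compare_models classifies sign-discordant genes", {
  mk <- function(genes, est, sig, model) {
    data.frame(gene = genes, tumor_type = "tt", model = model,
               estimate = est, se = 0.1, p = 0.001,
               padj = ifelse(sig, 0.001, 0.5),
               direction = ifelse(est >= 0, "up", "down"),
               significant = sig, stringsAsFactors = FALSE)
  }
  # FAT2-style (-1.80 adj vs +0.42 unadj) and FGFR2-style (+0.76 vs -0.52)
  adj <- mk(c("A", "B", "C"), c(-1.80, 0.76, 1.0), c(TRUE, TRUE, TRUE),
            "adjusted")
  unadj <- mk(c("A", "B", "C"), c(0.42, -0.52, 1.1), c(TRUE, TRUE, FALSE),
              "unadjusted")
  cmp <- compare_models(adj, unadj)
  expect_setequal(cmp$tt$discordant, c("A", "B"))
  expect_setequal(cmp$tt$adjusted_only, "C")
  expect_equal(unname(cmp$tt$estimate_ratio["A"]), 0.42 / -1.80)

  # identical tables: only the 'both' set is populated
  cmp2 <- compare_models(adj, adj)
  expect_length(cmp2$tt$adjusted_only, 0)
  expect_length(cmp2$tt$unadjusted_only, 0)
  expect_length(cmp2$tt$discordant, 0)
})
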