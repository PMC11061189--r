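test_that("vam_scores handles degenerate and single-gene sets", {
  set.seed(61)
  mat <- matrix(abs(rnorm(40 * 100)), nrow = 40,
                dimnames = list(sprintf("g%02d", 1:40), paste0("c", 1:100)))
  mat["g01", ] <- 0
  v <- vam_scores(mat, list(zero = "g01", single = "g02"),
                  n_null_perms = 20, seed = 1)
  # all-zero set: score 0, p 1
  expect_true(all(v$scores[, "zero"] == 0))
  expect_true(all(v$p[, "zero"] == 1))
  # single-gene set: score x^2 / var, monotone in |x|
  x <- mat["g02", ]
  expect_equal(unname(v$scores[, "single"]),
               unname(x^2 / var(x)), tolerance = 1e-12)
  ord <- order(abs(x))
  expect_true(all(diff(v$scores[ord, "single"]) >= 0))
})

test_that("VAM p-values are uniform under the null", {
  set.seed(62)
  n <- 3000
  mat <- matrix(abs(rnorm(50 * n)), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:n)))
  v <- vam_scores(mat, list(S = rownames(mat)[1:10]), n_null_perms = 50,
                  seed = 2)
  ks <- suppressWarnings(stats::ks.test(v$p[, "S"], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("gamma-fit p-values track empirical permutation p-values", {
  set.seed(63)
  n <- 400
  mat <- matrix(abs(rnorm(30 * n)), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), paste0("c", 1:n)))
  genes <- rownames(mat)[1:8]
  v <- vam_scores(mat, list(S = genes), n_null_perms = 1000, seed = 3)
  # empirical null from independent gene-wise permutations
  set.seed(99)
  w <- mat[genes, ] / sqrt(apply(mat[genes, ], 1, var))
  null_scores <- replicate(200, {
    colSums(t(apply(w, 1, sample))^2)
  })
  emp_p <- vapply(v$scores[, "S"], function(s) mean(null_scores >= s),
                  numeric(1))
  expect_lt(max(abs(emp_p - v$p[, "S"])), 0.02)
})

test_that("bh_adjust reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  p <- sort(runif(50))
  q <- bh_adjust(p)
  expect_true(all(diff(q) >= -1e-15))       # sorted in, sorted out
  expect_true(all(q >= p))                  # adjusted >= raw
  expect_true(all(q <= 1))
})

test_that("cell-type validation flags programmed signatures and stays calibrated", {
  set.seed(64)
  n_cells <- 400
  mat <- matrix(abs(rnorm(60 * n_cells)), nrow = 60,
                dimnames = list(sprintf("g%02d", 1:60),
                                paste0("c", 1:n_cells)))
  ast_genes <- rownames(mat)[1:8]
  ast_cells <- 1:150
  mat[ast_genes, ast_cells] <- mat[ast_genes, ast_cells] + 2
  flags <- celltype_validation(mat, list(AST = ast_genes,
                                         OTHER = rownames(mat)[31:38]),
                               n_null_perms = 50, seed = 4)
  expect_gt(mean(flags[ast_cells, "AST"]), 0.9)
  # null set: flag rate near the nominal 5%
  expect_lt(abs(mean(flags[, "OTHER"]) - 0.05), 0.04)
  # empty set never flags
  flags2 <- celltype_validation(mat, list(EMPTY = character(0)),
                                n_null_perms = 20, seed = 5)
  expect_false(any(flags2[, "EMPTY"]))
})

test_that("rank-sum on binary flags equals the two-proportion z-test", {
  set.seed(65)
  for (rep in 1:50) {
    n1 <- sample(10:80, 1); n2 <- sample(10:80, 1)
    x1 <- rbinom(1, n1, runif(1, 0.05, 0.9))
    x2 <- rbinom(1, n2, runif(1, 0.05, 0.9))
    flag <- c(rep(c(TRUE, FALSE), c(x1, n1 - x1)),
              rep(c(TRUE, FALSE), c(x2, n2 - x2)))
    in_cl <- rep(c(TRUE, FALSE), c(n1, n2))
    p_rank <- snpool:::ranksum_binary(in_cl, flag)
    p_z <- prop_ztest_p(x1, n1, x2, n2)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    expect_equal(p_rank, p_z, tolerance = 1e-6)
  }
})

test_that("differential enrichment reports positive, significant sets only", {
  set.seed(66)
  n <- 400
  clusters <- rep(0:1, each = n / 2)
  enr <- cbind(
    up = c(runif(n / 2) < 0.6, runif(n / 2) < 0.05),
    flat = runif(n) < 0.2,
    none = rep(FALSE, n)
  )
  rownames(enr) <- paste0("c", 1:n)
  de <- differential_enrichment(enr, clusters)
  r_up <- de[de$cluster == 0 & de$set == "up", ]
  expect_true(r_up$significant)
  expect_gt(r_up$avg_log2fc, 0)
  # two-proportion oracle agreement
  x1 <- sum(enr[clusters == 0, "up"]); x2 <- sum(enr[clusters == 1, "up"])
  expect_equal(r_up$p, prop_ztest_p(x1, n / 2, x2, n / 2), tolerance = 1e-6)
  # identical proportions: p near 1, never significant
  r_flat <- de[de$set == "flat", ]
  expect_true(all(!r_flat$significant | r_flat$avg_log2fc > 0))
  # all-zero set: fold change 0, not reported significant
  r_none <- de[de$set == "none", ]
  expect_true(all(r_none$avg_log2fc == 0))
  expect_false(any(r_none$significant, na.rm = TRUE))
  # the "up" enrichment of cluster 1 is negative-direction: not significant
  expect_false(de[de$cluster == 1 & de$set == "up", "significant"])

  tal <- enrichment_tally(de)
  expect_equal(tal$n_clusters_significant[tal$set == "up"], 1L)
})
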