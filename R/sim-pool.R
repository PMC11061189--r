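#' Simulate donor genotypes for a pool
#'
#' Draws a donor-by-SNP dosage matrix with dosages in \{0, 0.5, 1\}
#' (alternate-allele fraction coding), sampled uniformly and resampled
#' until every pair of donors differs at one or more SNPs, as bulk-derived
#' genotypes of unrelated donors would.
#'
#' @param config A [sim_config()].
#' @return Numeric matrix (donors x SNPs) with dosages in \{0, 0.5, 1\},
#'   rownames the sample ids, colnames SNP ids.
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples_per_pool = 3, n_snps = 20))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_snps < 1) stop("n_snps must be >= 1")
  if (config$n_samples_per_pool < 2) stop("need >= 2 samples to genotype a pool")
  if (3^config$n_snps < config$n_samples_per_pool) {
    stop("configuration error: ", config$n_snps,
         " SNPs cannot distinguish ", config$n_samples_per_pool, " donors")
  }
  K <- config$n_samples_per_pool
  with_seed(config$seed, {
    for (try in seq_len(1000L)) {
      g <- matrix(
        sample(c(0, 0.5, 1), K * config$n_snps, replace = TRUE),
        nrow = K,
        dimnames = list(config$samples,
                        sprintf("SNP%04d", seq_len(config$n_snps)))
      )
      if (all_donor_pairs_distinct(g)) return(g)
    }
    stop("configuration error: could not draw pairwise-distinct genotypes")
  })
}

all_donor_pairs_distinct <- function(g) {
  K <- nrow(g)
  if (K < 2) return(TRUE)
  for (i in seq_len(K - 1)) {
    for (j in seq((i + 1), K)) {
      if (all(g[i, ] == g[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Deterministic collision-free 16-mer barcodes from cell indices.
make_barcodes <- function(n) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(16)
    for (p in 16:1) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste(bases[digits + 1L], collapse = "")
  }, character(1))
}

# Per-(gene, cell type) expected counts implied by a sim_config: a shared
# lognormal baseline, marker genes boosted in their own type and suppressed
# elsewhere, mitochondrial genes scaled to the configured count fraction.
celltype_mean_matrix <- function(config) {
  genes <- config$genes
  mu <- matrix(exp(rnorm(length(genes), log(0.5), 0.5)),
               nrow = length(genes), ncol = config$n_celltypes,
               dimnames = list(genes, config$celltypes))
  for (ct in names(config$marker_table)) {
    mk <- config$marker_table[[ct]]
    mu[mk, ] <- 0.05
    if (ct %in% colnames(mu)) mu[mk, ct] <- config$marker_mean
  }
  if (length(config$mito_genes) > 0 && config$mito_fraction > 0) {
    non_mito <- setdiff(genes, config$mito_genes)
    for (ct in config$celltypes) {
      tot <- sum(mu[non_mito, ct])
      target <- config$mito_fraction / (1 - config$mito_fraction) * tot
      mu[config$mito_genes, ct] <- target / length(config$mito_genes)
    }
  }
  mu
}

#' Simulate a multiplexed single-nuclei pool with ground truth
#'
#' Generates one pooled droplet dataset: UMI counts with cell-type marker
#' programs and group-specific within-cell-type effects, hashtag-oligo tag
#' counts with configurable staining efficiency, and sparse per-cell SNP
#' allele counts consistent with the donor genotypes. Doublets carry two
#' nuclei: their expression is the sum of two singlet draws, both donors'
#' tags can be stained, and allele counts follow the mean of the two donor
#' dosages. Every droplet's true origin is recorded.
#'
#' The count model is negative binomial with mean \eqn{\mu} and variance
#' \eqn{\mu + \phi \mu^2} (`nb_dispersion` \eqn{\phi}). SNP read depth is
#' Poisson; given depth \eqn{d} and dosage \eqn{g}, alternate reads are
#' Binomial\eqn{(d, \epsilon + (1 - 2\epsilon) g)}.
#'
#' @param config A [sim_config()].
#' @param genotypes Optional donor-by-SNP dosage matrix; defaults to
#'   [simulate_genotypes()] under the same config.
#' @return A list of class `pool_sim` with elements `dataset` (class
#'   `pool_dataset`: `counts` genes x cells sparse matrix, `hto` tags x
#'   cells matrix, `tag_map`, `allele` with `ad`/`dp` SNP x cell matrices,
#'   `genotypes`, `samples`, `sample_groups`, `mito_genes`, `marker_table`,
#'   `gene_sets`) and `truth` (class `sim_truth`: one row per droplet with
#'   barcode, sample(s) of origin, doublet flag, cell type(s), group).
#' @examples
#' sim <- simulate_pool(sim_config(n_samples_per_pool = 2,
#'                                 n_nuclei_per_sample = 50, n_genes = 40))
#' table(sim$truth$sample1, sim$truth$doublet)
#' @export
simulate_pool <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genotypes)) genotypes <- simulate_genotypes(config)
  stopifnot(all(config$samples %in% rownames(genotypes)))

  K <- config$n_samples_per_pool
  N <- K * config$n_nuclei_per_sample
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf

  with_seed(config$seed + 1L, {
    barcodes <- make_barcodes(N)
    sample1 <- rep(config$samples, each = config$n_nuclei_per_sample)
    doublet <- runif(N) < config$doublet_rate
    sample2 <- rep(NA_character_, N)
    if (K >= 2 && any(doublet)) {
      sample2[doublet] <- vapply(sample1[doublet], function(s) {
        sample(setdiff(config$samples, s), 1L)
      }, character(1))
    } else {
      doublet[] <- doublet & FALSE
    }

    # cell types drawn per nucleus from its sample's group composition
    ct_for <- function(samps) {
      out <- character(length(samps))
      for (g in unique(config$sample_groups[samps])) {
        idx <- which(config$sample_groups[samps] == g)
        out[idx] <- sample(config$celltypes, length(idx), replace = TRUE,
                           prob = config$composition_by_group[[g]])
      }
      out
    }
    celltype1 <- ct_for(sample1)
    celltype2 <- rep(NA_character_, N)
    if (any(doublet)) celltype2[doublet] <- ct_for(sample2[doublet])

    mu_ct <- celltype_mean_matrix(config)

    # expected counts for one nucleus of (cell type, sample-group)
    component_mu <- function(ct, samp) {
      mu <- mu_ct[, ct, drop = FALSE]
      grp <- config$sample_groups[samp]
      eff <- config$de_effects[[grp]]
      if (!is.null(eff)) mu[names(eff), ] <- mu[names(eff), ] * exp(eff)
      mu
    }
    # components: one per nucleus (two for doublets)
    comp_cell <- c(seq_len(N), which(doublet))
    comp_samp <- c(sample1, sample2[doublet])
    comp_ct <- c(celltype1, celltype2[doublet])
    n_comp <- length(comp_cell)

    mu_mat <- matrix(0, nrow = length(config$genes), ncol = n_comp)
    key <- paste(comp_ct, config$sample_groups[comp_samp])
    for (k in unique(key)) {
      idx <- which(key == k)
      mu_mat[, idx] <- component_mu(comp_ct[idx[1]], comp_samp[idx[1]])[, 1]
    }
    counts_comp <- matrix(
      rnbinom(length(mu_mat), size = size, mu = mu_mat),
      nrow = nrow(mu_mat)
    )
    agg <- Matrix::sparseMatrix(i = seq_len(n_comp), j = comp_cell,
                                x = 1, dims = c(n_comp, N))
    counts <- methods::as(
      methods::as(Matrix::Matrix(counts_comp, sparse = TRUE) %*% agg,
                  "CsparseMatrix"),
      "dMatrix"
    )
    dimnames(counts) <- list(config$genes, barcodes)

    # HTO tag counts
    tags <- paste0("HTO", seq_len(K))
    tag_map <- setNames(config$samples, tags)
    hto <- matrix(
      rnbinom(K * N, size = size, mu = config$hto_background_mean),
      nrow = K, dimnames = list(tags, barcodes)
    )
    tag_of <- setNames(tags, config$samples)
    stained <- runif(n_comp) < config$hto_stain_efficiency
    sig_idx <- which(stained)
    if (length(sig_idx) > 0) {
      rows <- match(tag_of[comp_samp[sig_idx]], tags)
      cols <- comp_cell[sig_idx]
      hto[cbind(rows, cols)] <- rnbinom(length(sig_idx), size = size,
                                        mu = config$hto_signal_mean)
    }

    # per-cell SNP allele counts
    snps <- colnames(genotypes)
    if (config$n_snps > 0) {
      dp <- matrix(rpois(config$n_snps * N, config$snp_depth_mean),
                   nrow = config$n_snps, dimnames = list(snps, barcodes))
      dos1 <- t(genotypes[sample1, snps, drop = FALSE])
      dos <- dos1
      if (any(doublet)) {
        dos[, doublet] <- (dos1[, doublet, drop = FALSE] +
          t(genotypes[sample2[doublet], snps, drop = FALSE])) / 2
      }
      e <- config$allele_error
      mu_alt <- e + (1 - 2 * e) * dos
      ad <- matrix(rbinom(length(dp), size = dp, prob = mu_alt),
                   nrow = config$n_snps, dimnames = dimnames(dp))
      allele <- list(
        ad = methods::as(Matrix::Matrix(ad, sparse = TRUE), "CsparseMatrix"),
        dp = methods::as(Matrix::Matrix(dp, sparse = TRUE), "CsparseMatrix")
      )
    } else {
      allele <- list(
        ad = Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(0, N)),
        dp = Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(0, N))
      )
    }

    truth <- data.frame(
      barcode = barcodes,
      sample1 = sample1,
      sample2 = sample2,
      doublet = doublet,
      celltype1 = celltype1,
      celltype2 = celltype2,
      group = unname(config$sample_groups[sample1]),
      stringsAsFactors = FALSE
    )
    class(truth) <- c("sim_truth", "data.frame")

    dataset <- structure(
      list(
        counts = counts,
        hto = hto,
        tag_map = tag_map,
        allele = allele,
        genotypes = genotypes,
        samples = config$samples,
        sample_groups = config$sample_groups,
        mito_genes = config$mito_genes,
        marker_table = config$marker_table,
        gene_sets = config$gene_sets
      ),
      class = "pool_dataset"
    )
    structure(list(dataset = dataset, truth = truth), class = "pool_sim")
  })
}

#' @export
print.pool_dataset <- function(x, ...) {
  cat("pool_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      nrow(x$hto), "HTO tags;", nrow(x$allele$dp), "SNPs;",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Configuration for the composition-confounded expression simulation
#'
#' Defines the two-group, two-cell-type design used to demonstrate how
#' differing cell-type composition alone creates marginal between-group
#' differences: a tumor-like group with an 80/20 cell-type mix against a
#' non-tumor group with a 20/80 mix. Three gene classes are generated:
#' `effect` genes with a true within-cell-type log-fold-change in the tumor
#' group, `confounded_null` genes with zero within-type effect but strongly
#' cell-type-dependent baselines (mean 10 in the first type, 1 in the
#' second), and `background` genes with neither.
#'
#' @param n_cells_per_group Cells simulated per group.
#' @param groups Two or more group labels; the last is the non-tumor
#'   referent.
#' @param composition_by_group Named list of cell-type proportion vectors.
#' @param n_effect_genes,effect_lnfc Count and natural-log fold change of
#'   truly differential genes (applied within every cell type).
#' @param n_confounded_genes Count of zero-effect, composition-confounded
#'   genes.
#' @param confounded_means Baseline means of confounded genes in the two
#'   cell types.
#' @param n_background_genes Count of null genes with equal means in all
#'   cell types.
#' @param base_mean Baseline mean of effect and background genes.
#' @param nb_dispersion Negative-binomial dispersion.
#' @param seed Integer seed.
#' @return A list of class `confounded_config`.
#' @export
confounded_config <- function(n_cells_per_group = 1000,
                              groups = c("tumor", "nontumor"),
                              composition_by_group = list(
                                tumor = c(0.8, 0.2),
                                nontumor = c(0.2, 0.8)
                              ),
                              n_effect_genes = 100,
                              effect_lnfc = 1,
                              n_confounded_genes = 100,
                              confounded_means = c(10, 1),
                              n_background_genes = 100,
                              base_mean = 2,
                              nb_dispersion = 0.5,
                              seed = 1L) {
  stopifnot(length(groups) >= 2, n_cells_per_group >= 2,
            all(groups %in% names(composition_by_group)),
            length(confounded_means) == 2)
  for (g in groups) {
    p <- composition_by_group[[g]]
    stopifnot(length(p) == 2, all(p >= 0), abs(sum(p) - 1) < 1e-8)
  }
  structure(
    list(
      n_cells_per_group = as.integer(n_cells_per_group),
      groups = groups,
      composition_by_group = composition_by_group,
      n_effect_genes = as.integer(n_effect_genes),
      effect_lnfc = effect_lnfc,
      n_confounded_genes = as.integer(n_confounded_genes),
      confounded_means = confounded_means,
      n_background_genes = as.integer(n_background_genes),
      base_mean = base_mean,
      nb_dispersion = nb_dispersion,
      seed = as.integer(seed)
    ),
    class = "confounded_config"
  )
}

#' Simulate composition-confounded expression with known null genes
#'
#' Generates a dataset in which cell-type composition differs between
#' groups while a designated gene subset has no within-cell-type group
#' effect at all. Marginally those genes differ between groups (a pure
#' composition artifact), so truth-aware tests can quantify how much a
#' cell-type-adjusted differential-expression model removes the artifact
#' relative to an unadjusted one.
#'
#' @param config A [confounded_config()].
#' @return A list of class `confounded_sim` with `counts` (genes x cells
#'   sparse matrix), `cells` (data.frame: cell, group, celltype),
#'   `genes` (data.frame: gene, class, lnfc — class one of `effect`,
#'   `confounded_null`, `background`), and `size_factors` (all 1: cells
#'   are simulated at equal expected sequencing depth, so the matching
#'   GLM offset is constant).
#' @examples
#' sim <- simulate_confounded_expression(
#'   confounded_config(n_cells_per_group = 50, n_effect_genes = 5,
#'                     n_confounded_genes = 5, n_background_genes = 5))
#' table(sim$cells$group, sim$cells$celltype)
#' @export
simulate_confounded_expression <- function(config = confounded_config()) {
  stopifnot(inherits(config, "confounded_config"))
  celltypes <- c("CT1", "CT2")
  n_genes <- config$n_effect_genes + config$n_confounded_genes +
    config$n_background_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  gene_class <- rep(c("effect", "confounded_null", "background"),
                    c(config$n_effect_genes, config$n_confounded_genes,
                      config$n_background_genes))
  lnfc <- ifelse(gene_class == "effect", config$effect_lnfc, 0)

  # per-(gene, cell type) baseline means
  mu_ct <- matrix(config$base_mean, nrow = n_genes, ncol = 2,
                  dimnames = list(genes, celltypes))
  mu_ct[gene_class == "confounded_null", 1] <- config$confounded_means[1]
  mu_ct[gene_class == "confounded_null", 2] <- config$confounded_means[2]

  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  referent <- config$groups[length(config$groups)]

  with_seed(config$seed, {
    cells <- data.frame(
      cell = character(0), group = character(0), celltype = character(0),
      stringsAsFactors = FALSE
    )
    counts_blocks <- list()
    offset <- 0L
    for (g in config$groups) {
      ct <- sample(celltypes, config$n_cells_per_group, replace = TRUE,
                   prob = config$composition_by_group[[g]])
      mu <- mu_ct[, ct, drop = FALSE]
      if (g != referent) {
        mu <- mu * exp(matrix(lnfc, nrow = n_genes, ncol = length(ct)))
      }
      block <- matrix(rnbinom(length(mu), size = size, mu = mu),
                      nrow = n_genes)
      counts_blocks[[g]] <- block
      cells <- rbind(cells, data.frame(
        cell = sprintf("%s_c%05d", g, seq_along(ct) + offset),
        group = g, celltype = ct, stringsAsFactors = FALSE
      ))
      offset <- offset + length(ct)
    }
    counts <- do.call(cbind, counts_blocks)
    dimnames(counts) <- list(genes, cells$cell)
    structure(
      list(
        counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                             "CsparseMatrix"),
        cells = cells,
        genes = data.frame(gene = genes, class = gene_class, lnfc = lnfc,
                           stringsAsFactors = FALSE),
        size_factors = setNames(rep(1, nrow(cells)), cells$cell),
        referent = referent,
        config = config
      ),
      class = "confounded_sim"
    )
  })
}
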