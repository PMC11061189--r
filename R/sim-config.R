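#' Simulation configuration for a multiplexed single-nuclei pool
#'
#' Collects every parameter of the synthetic pool generator: pool design
#' (samples per pool, nuclei per sample, doublet rate), donor genotypes
#' (number of SNPs, per-cell sequencing depth, allele error), hashtag-oligo
#' staining (signal and background negative-binomial means, staining
#' efficiency), and the expression model (genes, cell types, per-group
#' cell-type composition, within-cell-type differential effects, marker
#' programs, negative-binomial dispersion, mitochondrial content).
#'
#' Defaults follow the pooled study design the generator emulates: 2-4
#' samples per pool at 2500 nuclei per sample, a 5% doublet rate, sparse
#' SNP coverage (50 sites at mean depth 2), and deliberately imperfect HTO
#' staining (70% of nuclei receive signal-level tag counts) so that the
#' genotype-rescue pathway of integrated demultiplexing is exercised.
#'
#' @param n_samples_per_pool Number of samples multiplexed in the pool.
#' @param n_nuclei_per_sample Nuclei contributed by each sample (droplets
#'   whose primary nucleus comes from that sample).
#' @param doublet_rate Fraction of droplets carrying a second nucleus;
#'   must be below 0.5.
#' @param n_snps Number of donor-discriminating SNP sites.
#' @param snp_depth_mean Mean reads per SNP per cell (Poisson).
#' @param allele_error Per-read allele error rate \eqn{\epsilon \in [0, 0.5)}.
#' @param hto_signal_mean,hto_background_mean Negative-binomial means of
#'   the sample's own tag (when stained) and of off-target tags.
#' @param hto_stain_efficiency Probability a nucleus receives signal-level
#'   counts for its own tag; lowering this reproduces the weak-staining
#'   failure mode that motivates genotype rescue.
#' @param n_genes Total genes, including `n_mito_genes` mitochondrial genes.
#' @param n_celltypes Number of cell types with distinct marker programs.
#' @param sample_groups Character vector (length `n_samples_per_pool`)
#'   assigning each sample to a group (tumor type or `"nontumor"`).
#'   Default: all samples `"tumor"` except the last, which is `"nontumor"`.
#' @param composition_by_group Named list mapping each group to a cell-type
#'   proportion vector (length `n_celltypes`, summing to 1). Default uniform.
#' @param de_effects Named list mapping a group to a named numeric vector of
#'   within-cell-type natural-log fold changes (gene id -> lnFC) applied to
#'   cells of that group. Default: none.
#' @param marker_table Named list mapping cell type to marker gene ids.
#'   Default: two dedicated marker genes per type.
#' @param gene_sets Named list of gene sets shipped with the simulated data
#'   (used by enrichment stages). Default: the marker programs.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   \eqn{\mu + \phi\mu^2}) for tag and UMI counts.
#' @param mito_fraction Expected fraction of a nucleus' reads mapping to
#'   mitochondrial genes.
#' @param n_mito_genes Number of flagged mitochondrial genes.
#' @param marker_mean Mean expression of a marker gene in its own cell type
#'   (off-type marker mean is 0.05).
#' @param seed Integer seed; a fixed config and seed give byte-identical
#'   simulated datasets.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_samples_per_pool = 2, n_nuclei_per_sample = 100)
#' cfg$samples
#' @export
sim_config <- function(n_samples_per_pool = 4,
                       n_nuclei_per_sample = 2500,
                       doublet_rate = 0.05,
                       n_snps = 50,
                       snp_depth_mean = 2,
                       allele_error = 0.01,
                       hto_signal_mean = 200,
                       hto_background_mean = 5,
                       hto_stain_efficiency = 0.7,
                       n_genes = 300,
                       n_celltypes = 4,
                       sample_groups = NULL,
                       composition_by_group = NULL,
                       de_effects = NULL,
                       marker_table = NULL,
                       gene_sets = NULL,
                       nb_dispersion = 0.5,
                       mito_fraction = 0.02,
                       n_mito_genes = 10,
                       marker_mean = 5,
                       seed = 1L) {
  stopifnot(
    n_samples_per_pool >= 1, n_nuclei_per_sample >= 1,
    n_snps >= 0, n_genes >= 1, n_celltypes >= 1,
    n_mito_genes >= 0, n_mito_genes < n_genes
  )
  if (doublet_rate < 0 || doublet_rate >= 0.5) {
    stop("`doublet_rate` must lie in [0, 0.5)")
  }
  if (allele_error < 0 || allele_error >= 0.5) {
    stop("`allele_error` must lie in [0, 0.5)")
  }
  if (hto_stain_efficiency < 0 || hto_stain_efficiency > 1) {
    stop("`hto_stain_efficiency` must lie in [0, 1]")
  }
  if (mito_fraction < 0 || mito_fraction >= 1) {
    stop("`mito_fraction` must lie in [0, 1)")
  }
  for (m in c(snp_depth_mean, hto_signal_mean, hto_background_mean,
              nb_dispersion, marker_mean)) {
    if (m < 0) stop("rate/mean parameters must be nonnegative")
  }

  samples <- paste0("S", seq_len(n_samples_per_pool))
  celltypes <- paste0("CT", seq_len(n_celltypes))
  n_regular <- n_genes - n_mito_genes
  genes <- c(
    sprintf("G%04d", seq_len(n_regular)),
    if (n_mito_genes > 0) sprintf("MT-%02d", seq_len(n_mito_genes))
  )
  mito_genes <- genes[grepl("^MT-", genes)]

  if (is.null(sample_groups)) {
    sample_groups <- rep("tumor", n_samples_per_pool)
    if (n_samples_per_pool >= 2) {
      sample_groups[n_samples_per_pool] <- "nontumor"
    }
  }
  stopifnot(length(sample_groups) == n_samples_per_pool)
  names(sample_groups) <- samples
  groups <- unique(sample_groups)

  if (is.null(composition_by_group)) {
    composition_by_group <- lapply(
      setNames(groups, groups),
      function(g) rep(1 / n_celltypes, n_celltypes)
    )
  }
  stopifnot(all(groups %in% names(composition_by_group)))
  for (g in names(composition_by_group)) {
    p <- composition_by_group[[g]]
    if (length(p) != n_celltypes || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-8) {
      stop("composition for group '", g,
           "' must be ", n_celltypes, " proportions summing to 1")
    }
    names(composition_by_group[[g]]) <- celltypes
  }

  if (is.null(marker_table)) {
    if (2 * n_celltypes > n_regular) {
      stop("not enough non-mitochondrial genes for default marker table")
    }
    marker_table <- lapply(
      setNames(seq_len(n_celltypes), celltypes),
      function(k) genes[c(2 * k - 1, 2 * k)]
    )
  }
  stopifnot(all(unlist(marker_table) %in% genes))

  if (is.null(gene_sets)) {
    gene_sets <- setNames(marker_table, paste0(names(marker_table), "_program"))
  }

  de_effects <- de_effects %||% list()
  for (g in names(de_effects)) {
    if (!g %in% groups) stop("de_effects group '", g, "' not in sample_groups")
    if (is.null(names(de_effects[[g]])) ||
        !all(names(de_effects[[g]]) %in% genes)) {
      stop("de_effects for group '", g, "' must be named by gene id")
    }
  }

  structure(
    list(
      n_samples_per_pool = as.integer(n_samples_per_pool),
      n_nuclei_per_sample = as.integer(n_nuclei_per_sample),
      doublet_rate = doublet_rate,
      n_snps = as.integer(n_snps),
      snp_depth_mean = snp_depth_mean,
      allele_error = allele_error,
      hto_signal_mean = hto_signal_mean,
      hto_background_mean = hto_background_mean,
      hto_stain_efficiency = hto_stain_efficiency,
      n_genes = as.integer(n_genes),
      n_celltypes = as.integer(n_celltypes),
      samples = samples,
      celltypes = celltypes,
      genes = genes,
      mito_genes = mito_genes,
      sample_groups = sample_groups,
      composition_by_group = composition_by_group,
      de_effects = de_effects,
      marker_table = marker_table,
      gene_sets = gene_sets,
      nb_dispersion = nb_dispersion,
      mito_fraction = mito_fraction,
      marker_mean = marker_mean,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples_per_pool, "samples x",
      x$n_nuclei_per_sample, "nuclei,",
      x$n_genes, "genes,", x$n_celltypes, "cell types, doublet rate",
      x$doublet_rate, "\n")
  invisible(x)
}
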