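#' Variance-adjusted Mahalanobis gene-set scores per cell
#'
#' For gene set \eqn{P}, each cell's score is the squared distance from
#' the origin of its normalized expression over the set genes, scaled by
#' per-gene variances: \eqn{S_{cP} = \sum_{j \in P} x_{cj}^2 / v_j} with
#' \eqn{v_j} the sample variance of gene \eqn{j} across cells (floored at
#' 1e-8). P-values come from a gamma null fitted by method of moments to
#' scores computed after independently permuting each set gene's values
#' across cells (`n_null_perms` permutations, seeded);
#' \eqn{p = 1 - F_\Gamma(S)}. Per set, p-values are BH-adjusted across
#' cells and a cell is flagged enriched when the adjusted p falls below
#' `fdr_threshold`.
#'
#' @param normalized A [normalize_log()] result or genes x cells matrix.
#' @param gene_sets Named list of gene-id vectors (intersected with
#'   features; sets with an empty intersection get p = 1 everywhere).
#' @param n_null_perms Number of gene-wise permutations for the null
#'   (default 100).
#' @param fdr_threshold Adjusted-p cutoff for the binary enrichment flag
#'   (default 0.1).
#' @param seed Seed for the permutation null.
#' @return A list of class `enrichment_matrix` with cell x set matrices
#'   `scores`, `p`, `padj`, `enriched`, and `null_params` (per-set gamma
#'   shape/rate).
#' @export
vam_scores <- function(normalized, gene_sets, n_null_perms = 100,
                       fdr_threshold = 0.1, seed = 1L) {
  mat <- if (inherits(normalized, "normalized_matrix")) normalized$mat
         else normalized
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  n_cells <- ncol(mat)
  cells <- colnames(mat) %||% as.character(seq_len(n_cells))
  sets <- names(gene_sets)

  scores <- p <- padj <- matrix(NA_real_, nrow = n_cells, ncol = length(sets),
                                dimnames = list(cells, sets))
  null_params <- matrix(NA_real_, nrow = length(sets), ncol = 2,
                        dimnames = list(sets, c("shape", "rate")))

  with_seed(seed, {
    for (s in sets) {
      genes <- intersect(gene_sets[[s]], rownames(mat))
      if (length(genes) == 0) {
        scores[, s] <- 0; p[, s] <- 1
        next
      }
      x <- as.matrix(mat[genes, , drop = FALSE])
      v <- pmax(apply(x, 1, var), 1e-8)
      w <- x / sqrt(v)
      scores[, s] <- colSums(w^2)

      if (all(x == 0)) {
        p[, s] <- 1
        next
      }
      null_scores <- numeric(n_cells * n_null_perms)
      for (b in seq_len(n_null_perms)) {
        wp <- t(apply(w, 1, sample))
        null_scores[((b - 1) * n_cells + 1):(b * n_cells)] <- colSums(wp^2)
      }
      m <- mean(null_scores)
      vv <- var(null_scores)
      if (!is.finite(vv) || vv <= 0) {
        p[, s] <- 1
        next
      }
      shape <- m^2 / vv
      rate <- m / vv
      null_params[s, ] <- c(shape, rate)
      p[, s] <- pgamma(scores[, s], shape = shape, rate = rate,
                       lower.tail = FALSE)
    }
  })
  for (s in sets) padj[, s] <- bh_adjust(p[, s])
  structure(
    list(scores = scores, p = p, padj = padj,
         enriched = padj < fdr_threshold,
         null_params = null_params, fdr_threshold = fdr_threshold),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix:", nrow(x$scores), "cells x", ncol(x$scores),
      "sets; FDR threshold", x$fdr_threshold, "\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjusted p-values (monotone, capped at 1), as used for
#' every multiple-testing family in the package.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' Cell-type association flags from VAM p-values
#'
#' A cell is flagged associated with a cell-type gene set when the
#' unadjusted VAM p-value is at or below `alpha` (default 0.05), the rule
#' used to validate marker-based cluster annotations.
#'
#' @param normalized A [normalize_log()] result or genes x cells matrix.
#' @param celltype_gene_sets Named list: cell type -> gene set.
#' @param alpha Unadjusted p cutoff (default 0.05, inclusive).
#' @param ... Passed to [vam_scores()].
#' @return Logical cell x type matrix of association flags, with the
#'   underlying `enrichment_matrix` attached as attribute `vam`.
#' @export
celltype_validation <- function(normalized, celltype_gene_sets,
                                alpha = 0.05, ...) {
  vam <- vam_scores(normalized, celltype_gene_sets, ...)
  flags <- vam$p <= alpha
  empty <- vapply(celltype_gene_sets, length, integer(1)) == 0
  flags[, names(celltype_gene_sets)[empty]] <- FALSE
  attr(flags, "vam") <- vam
  flags
}

# Tie-corrected normal-approximation Wilcoxon rank-sum test of a binary
# indicator, cluster vs rest. On 0/1 data this coincides with the
# tie-corrected two-proportion z-test.
ranksum_binary <- function(in_cluster, flag) {
  n <- length(flag)
  n1 <- sum(in_cluster)
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(flag)  # ties get average ranks
  W <- sum(r[in_cluster])
  mu <- n1 * (n + 1) / 2
  ties <- table(flag)
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (W - mu) / sqrt(v)
  2 * pnorm(-abs(z))
}

#' Differential pathway enrichment per cluster
#'
#' For each cluster and gene set, tests the binary per-cell enrichment
#' indicator of the cluster against all other cells with a tie-corrected
#' Wilcoxon rank-sum test (normal approximation), computes the average
#' log2 fold change of enrichment proportions with pseudocount `pseudo`,
#' and BH-adjusts p-values within each cluster. A result is marked
#' significant when the adjusted p is below `alpha` and the fold change is
#' positive; clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param enriched Logical cell x set matrix (e.g. the `enriched` slot of
#'   [vam_scores()]).
#' @param clusters Cluster labels aligned to the rows of `enriched`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param pseudo Pseudocount for the proportion fold change (default 1e-3).
#' @param global_bh When `TRUE`, BH-adjust across all (cluster, set) tests
#'   instead of within cluster.
#' @return data.frame of class `diff_enrich`: `cluster`, `set`,
#'   `prop_cluster`, `prop_rest`, `avg_log2fc`, `p`, `padj`,
#'   `significant`.
#' @export
differential_enrichment <- function(enriched, clusters, alpha = 0.05,
                                    pseudo = 1e-3, global_bh = FALSE) {
  stopifnot(nrow(enriched) == length(clusters))
  cl_levels <- sort(unique(clusters))
  if (length(cl_levels) < 2) stop("need >= 2 clusters")
  rows <- list()
  for (cl in cl_levels) {
    in_cl <- clusters == cl
    if (sum(in_cl) < 3) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    for (s in colnames(enriched)) {
      flag <- enriched[, s]
      p1 <- mean(flag[in_cl])
      p2 <- mean(flag[!in_cl])
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, set = s,
        prop_cluster = p1, prop_rest = p2,
        avg_log2fc = log2((p1 + pseudo) / (p2 + pseudo)),
        p = ranksum_binary(in_cl, flag),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (global_bh) {
    out$padj <- bh_adjust(out$p)
  } else {
    out$padj <- NA_real_
    for (cl in unique(out$cluster)) {
      i <- out$cluster == cl
      out$padj[i] <- bh_adjust(out$p[i])
    }
  }
  out$significant <- out$padj < alpha & out$avg_log2fc > 0
  class(out) <- c("diff_enrich", "data.frame")
  out
}

#' Cross-cluster tally of significant pathway enrichment
#'
#' Convenience report: for each gene set, the number of clusters in which
#' it is significantly (positively) enriched.
#'
#' @param diff A [differential_enrichment()] result.
#' @return data.frame with `set` and `n_clusters_significant`, sorted
#'   decreasingly.
#' @export
enrichment_tally <- function(diff) {
  tab <- tapply(diff$significant, diff$set, sum)
  out <- data.frame(set = names(tab),
                    n_clusters_significant = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_clusters_significant, out$set), , drop = FALSE]
}
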