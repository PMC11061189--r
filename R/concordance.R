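#' Expected proportion of all-concordant direction patterns
#'
#' Under an equal-probability null, a gene significant in all \eqn{T}
#' tumor-type contrasts takes one of \eqn{2^T} equiprobable up/down
#' direction patterns; exactly two of them (all up, all down) are fully
#' concordant, so the expected all-concordant proportion is
#' \eqn{2/2^T = 2^{1-T}}. For six tumor types this is 0.03125 (3.13%).
#'
#' @param n_types Number of tumor-type contrasts \eqn{T \ge 1}.
#' @return The expected proportion (a fraction, not a percentage).
#' @examples
#' expected_concordance(6)  # 0.03125
#' @export
expected_concordance <- function(n_types) {
  if (n_types < 1) stop("n_types must be >= 1")
  2 / 2^n_types
}

#' Cross-tumor-type direction concordance of differential expression
#'
#' Tallies, over a shared gene universe, how many genes are significant
#' in exactly k of the T tumor-type contrasts; among genes significant in
#' all T, counts those whose direction of change is identical in every
#' contrast, and compares the observed all-concordant proportion with the
#' permutation-null expectation \eqn{2^{1-T}} by a one-sample proportion
#' test.
#'
#' @param de A [run_de()] result (one model) covering all tumor types, or
#'   a data.frame with columns `gene`, `tumor_type`, `direction`,
#'   `significant`.
#' @return A list of class `concordance_result`: `n_types`, `per_k`
#'   (named counts of genes significant in exactly k types), `n_all`,
#'   `n_same_direction`, `observed_proportion`, `expected_proportion`,
#'   `statistic`, `p_value`, `p_display`.
#' @export
direction_concordance <- function(de) {
  stopifnot(all(c("gene", "tumor_type", "direction", "significant")
                %in% names(de)))
  types <- sort(unique(de$tumor_type))
  T <- length(types)
  genes <- sort(unique(de$gene))
  sig <- matrix(FALSE, nrow = length(genes), ncol = T,
                dimnames = list(genes, types))
  dir <- matrix(NA_character_, nrow = length(genes), ncol = T,
                dimnames = list(genes, types))
  for (tt in types) {
    sub <- de[de$tumor_type == tt, ]
    sig[sub$gene, tt] <- sub$significant
    dir[sub$gene, tt] <- sub$direction
  }
  k <- rowSums(sig)
  per_k <- table(factor(k, levels = 0:T))
  all_t <- names(k)[k == T]
  n_all <- length(all_t)
  n_same <- if (n_all > 0) {
    sum(apply(dir[all_t, , drop = FALSE], 1,
              function(d) length(unique(d)) == 1))
  } else 0L

  expected <- expected_concordance(T)
  if (n_all > 0) {
    pt_res <- proportion_test(n_same, n_all, expected)
    observed <- n_same / n_all
  } else {
    pt_res <- list(statistic = NA_real_, p_value = NA_real_,
                   p_display = NA_character_)
    observed <- NA_real_
  }
  structure(
    list(
      n_types = T,
      per_k = setNames(as.integer(per_k), names(per_k)),
      n_all = n_all,
      n_same_direction = n_same,
      observed_proportion = observed,
      expected_proportion = expected,
      statistic = pt_res$statistic,
      p_value = pt_res$p_value,
      p_display = pt_res$p_display
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("direction concordance over", x$n_types, "tumor types\n")
  cat("  genes significant in exactly k types:\n")
  for (k in names(x$per_k)) cat("    k =", k, ":", x$per_k[[k]], "\n")
  if (x$n_all > 0) {
    cat(sprintf(
      "  all-type genes: %d; same direction: %d (%.1f%% observed vs %.2f%% expected), p %s\n",
      x$n_all, x$n_same_direction, 100 * x$observed_proportion,
      100 * x$expected_proportion, x$p_display))
  }
  invisible(x)
}

#' One-sample proportion test
#'
#' Chi-square test (with Yates continuity correction by default, the
#' standard single-proportion test) of k successes in n trials against
#' null proportion p0. The exact p-value is stored; the display string
#' follows the conventional reporting floor of 2.2e-16.
#'
#' @param k Successes.
#' @param n Trials (> 0).
#' @param p0 Null proportion in (0, 1).
#' @param correct Apply continuity correction (default `TRUE`).
#' @return List: `statistic` (chi-square), `p_value` (exact), `p_display`
#'   (string, floored at `"< 2.2e-16"`), `estimate` (k/n).
#' @examples
#' proportion_test(340, 558, 0.03125)
#' @export
proportion_test <- function(k, n, p0, correct = TRUE) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (n == 0) stop("n must be positive")
  res <- prop.test(k, n, p = p0, correct = correct)
  p <- res$p.value
  list(
    statistic = unname(res$statistic),
    p_value = p,
    p_display = if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 3),
    estimate = k / n
  )
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability that the overlap between a hit
#' list and a gene set is at least as large as observed, within a fixed
#' gene universe: \eqn{P(X \ge o)} with X hypergeometric. When a list of
#' sets is supplied, p-values are BH-adjusted across sets.
#'
#' @param hits Character vector of hit genes (subset of `universe`).
#' @param gene_set A gene-id vector, or a named list of them.
#' @param universe Character vector, the tested gene universe.
#' @return For a single set, a list `overlap`, `p`; for a list of sets, a
#'   data.frame with `set`, `overlap`, `set_size`, `p`, `padj`.
#' @examples
#' hypergeom_ora(letters[1:5], letters[1:5], letters[1:10])  # 1/choose(10,5)
#' @export
hypergeom_ora <- function(hits, gene_set, universe) {
  if (length(universe) == 0) stop("empty universe")
  stopifnot(all(hits %in% universe))
  one <- function(set) {
    set <- intersect(set, universe)
    o <- length(intersect(hits, set))
    p <- phyper(o - 1, length(set), length(universe) - length(set),
                length(hits), lower.tail = FALSE)
    list(overlap = o, set_size = length(set), p = p)
  }
  if (is.list(gene_set)) {
    stopifnot(!is.null(names(gene_set)))
    rows <- lapply(gene_set, one)
    out <- data.frame(
      set = names(gene_set),
      overlap = vapply(rows, `[[`, integer(1) + 0, "overlap"),
      set_size = vapply(rows, `[[`, integer(1) + 0, "set_size"),
      p = vapply(rows, `[[`, numeric(1), "p"),
      stringsAsFactors = FALSE
    )
    out$padj <- bh_adjust(out$p)
    rownames(out) <- NULL
    out
  } else {
    r <- one(gene_set)
    list(overlap = r$overlap, p = r$p)
  }
}
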