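#' Nucleus quality-control thresholds
#'
#' Bounds on detected features and mitochondrial read fraction used to
#' drop low-quality or damaged nuclei. Defaults keep nuclei with more
#' than 200 and fewer than 10,000 detected features and under 5% of
#' counts in mitochondrial genes; all three bounds are strict
#' inequalities.
#'
#' @param min_features Lower bound on detected features (exclusive).
#' @param max_features Upper bound on detected features (exclusive).
#' @param max_mito_fraction Upper bound on mitochondrial count fraction
#'   (exclusive).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 10000,
                          max_mito_fraction = 0.05) {
  stopifnot(min_features < max_features,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_features = min_features, max_features = max_features,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Filter low-quality nuclei
#'
#' A nucleus is kept iff its detected-feature count lies strictly between
#' `min_features` and `max_features` and its mitochondrial count fraction
#' is strictly below `max_mito_fraction`.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param mito_genes Character vector of mitochondrial gene ids (must be a
#'   subset of `rownames(counts)`).
#' @param thresholds A [qc_thresholds()].
#' @return Named logical vector over cells: `TRUE` for kept nuclei.
#' @examples
#' m <- matrix(rpois(200, 2), nrow = 20,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
#' keep <- qc_filter(m, mito_genes = character(0),
#'                   thresholds = qc_thresholds(min_features = 5))
#' @export
qc_filter <- function(counts, mito_genes = character(0),
                      thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!all(mito_genes %in% rownames(counts))) {
    stop("mito_genes must be a subset of rownames(counts)")
  }
  n_features <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- if (length(mito_genes) > 0) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  mito_frac <- ifelse(total > 0, mito / total, 0)
  keep <- n_features > thresholds$min_features &
    n_features < thresholds$max_features &
    mito_frac < thresholds$max_mito_fraction
  names(keep) <- colnames(counts)
  if (!any(keep)) warning("QC filter removed every cell")
  keep
}

#' Median-ratio log normalization
#'
#' Computes \eqn{x_{cg} = \ln(1 + n_{cg} \bar{s} / s_c)} where
#' \eqn{s_c} is the total count of cell \eqn{c} and \eqn{\bar{s}} the
#' median total across cells. The per-cell size factor \eqn{s_c/\bar{s}}
#' is retained for use as a GLM offset in differential expression.
#'
#' @param counts Genes x cells nonnegative count matrix.
#' @return A list of class `normalized_matrix`: `mat` (genes x cells log
#'   normalized values), `size_factors` (per-cell \eqn{s_c/\bar{s}}),
#'   `scheme`. Cells with zero total counts are dropped with a warning.
#' @examples
#' m <- matrix(c(1, 0, 2, 4, 0, 8), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' nm <- normalize_log(m)
#' @export
normalize_log <- function(counts) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    warning(sum(total == 0), " zero-total cell(s) excluded from normalization")
    counts <- counts[, total > 0, drop = FALSE]
    total <- total[total > 0]
  }
  s_bar <- median(total)
  sf <- total / s_bar
  mat <- counts %*% Matrix::Diagonal(x = 1 / sf)
  colnames(mat) <- colnames(counts)
  mat@x <- log1p(mat@x)
  structure(
    list(mat = mat, size_factors = setNames(sf, colnames(counts)),
         scheme = "median-ratio log1p"),
    class = "normalized_matrix"
  )
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$scheme, "): ", nrow(x$mat), " genes x ",
      ncol(x$mat), " cells\n", sep = "")
  invisible(x)
}

#' Rank highly variable genes by standardized variance
#'
#' Fits a robust local-regression mean-variance trend (log variance on
#' log mean, symmetric-family loess so a minority of genuinely variable
#' genes does not inflate the trend), standardizes each gene's counts by
#' the trend-expected standard deviation, clips the standardized values
#' at \eqn{\sqrt{N}}, and ranks genes by the variance of the clipped
#' values. Ties are broken lexicographically by gene id, so the ranking
#' is deterministic.
#'
#' @param counts Genes x cells raw count matrix.
#' @param n_top Number of genes to return (at most `nrow(counts)`).
#' @param loess_span Span of the variance-trend local regression.
#' @return Character vector of the `n_top` gene ids, ordered from most to
#'   least variable.
#' @export
select_hvg <- function(counts, n_top, loess_span = 1) {
  stopifnot(n_top <= nrow(counts), n_top >= 1)
  n <- ncol(counts)
  mu <- Matrix::rowMeans(counts)
  v <- Matrix::rowMeans(counts^2) - mu^2
  v <- v * n / max(1, n - 1)

  std_var <- rep(0, nrow(counts))
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 5) {
    fit <- loess(log10(v[usable]) ~ log10(mu[usable]), span = loess_span,
                 degree = 1, family = "symmetric")
    exp_sd <- sqrt(10^fitted(fit))
    clip <- sqrt(n)
    dense <- as.matrix(counts[usable, , drop = FALSE])
    z <- (dense - mu[usable]) / exp_sd
    z <- pmin(pmax(z, -clip), clip)
    std_var[usable] <- rowSums((z - rowMeans(z))^2) / max(1, n - 1)
  } else if (any(usable)) {
    std_var[usable] <- v[usable]
  }
  names(std_var) <- rownames(counts)
  ord <- order(-std_var, names(std_var))
  names(std_var)[ord][seq_len(n_top)]
}
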