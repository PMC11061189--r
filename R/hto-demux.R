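#' Centered log-ratio normalization of hashtag counts
#'
#' For each tag, computes \eqn{\mathrm{clr}_{ct} = \ln(x_{ct}+1) -
#' \mathrm{mean}_c \ln(x_{ct}+1)}: the log1p counts centered across cells
#' within each tag (the margin used by current hashing classifiers).
#'
#' @param hto Tags x cells nonnegative count matrix with at least 2 tags.
#' @return Tags x cells numeric matrix of CLR values.
#' @examples
#' m <- rbind(HTO1 = c(0, exp(1) - 1), HTO2 = c(5, 5))
#' clr_normalize(m)
#' @export
clr_normalize <- function(hto) {
  hto <- as.matrix(hto)
  if (nrow(hto) < 2) stop("clr_normalize needs >= 2 tags")
  if (ncol(hto) < 2) {
    warning("single-cell pool: CLR is degenerate, returning zeros")
    return(hto * 0)
  }
  l <- log1p(hto)
  l - rowMeans(l)
}

# Method-of-moments negative-binomial quantile for background counts;
# falls back to Poisson when the background is underdispersed.
nb_background_cutoff <- function(x, q) {
  m <- mean(x)
  v <- var(x)
  if (m == 0) return(0)
  if (is.na(v) || v <= m) return(qpois(q, m))
  size <- m^2 / (v - m)
  qnbinom(q, size = size, mu = m)
}

#' Classify nuclei from hashtag-oligo counts
#'
#' Re-implements the standard hashing classifier: cells are partitioned on
#' their CLR profiles into K+1 groups (K = number of tags) by k-medoids;
#' for each tag, the group with the lowest mean count is taken as that
#' tag's background, a negative binomial is fitted to the background raw
#' counts by method of moments (Poisson fallback when underdispersed), and
#' a cell is positive for the tag when its raw count exceeds the fitted
#' `positive_quantile`. Cells positive for exactly one tag are singlets of
#' the mapped sample, for two or more tags doublets, for none negatives.
#'
#' @param hto Tags x cells count matrix.
#' @param tag_map Named character vector mapping tag id to sample id
#'   (names = rownames of `hto`).
#' @param positive_quantile Background quantile above which a raw count is
#'   called positive; in (0.5, 1), default 0.99.
#' @param seed Seed for the k-medoids partition.
#' @return A data.frame of class `hto_calls` with columns `cell`, `label`
#'   (sample id, `"DOUBLET"` or `"NEGATIVE"`) and `margin` (top CLR minus
#'   second CLR); the per-tag positivity matrix is attached as attribute
#'   `positive`.
#' @export
classify_hto <- function(hto, tag_map = NULL,
                         positive_quantile = 0.99, seed = 1L) {
  stopifnot(positive_quantile > 0.5, positive_quantile < 1)
  hto <- as.matrix(hto)
  K <- nrow(hto)
  if (is.null(tag_map)) tag_map <- setNames(rownames(hto), rownames(hto))
  stopifnot(all(rownames(hto) %in% names(tag_map)))
  n <- ncol(hto)
  if (any(Matrix::rowSums(hto) == 0)) {
    warning("tag(s) with all-zero counts can never be positive: ",
            paste(rownames(hto)[Matrix::rowSums(hto) == 0], collapse = ", "))
  }

  clr <- clr_normalize(hto)
  k_clust <- min(K + 1L, n - 1L)
  clusters <- with_seed(seed, {
    if (n > 2000) {
      cluster::clara(t(clr), k = k_clust, samples = 10,
                     pamLike = TRUE)$clustering
    } else {
      cluster::pam(t(clr), k = k_clust, cluster.only = TRUE)
    }
  })

  positive <- matrix(FALSE, nrow = K, ncol = n, dimnames = dimnames(hto))
  for (t in seq_len(K)) {
    cl_means <- tapply(hto[t, ], clusters, mean)
    bg_cluster <- as.integer(names(cl_means)[which.min(cl_means)])
    bg <- hto[t, clusters == bg_cluster]
    cutoff <- nb_background_cutoff(bg, positive_quantile)
    positive[t, ] <- hto[t, ] > cutoff
  }

  n_pos <- colSums(positive)
  label <- character(n)
  label[n_pos == 0] <- "NEGATIVE"
  label[n_pos >= 2] <- "DOUBLET"
  single <- which(n_pos == 1)
  if (length(single) > 0) {
    tag_idx <- apply(positive[, single, drop = FALSE], 2, which)
    label[single] <- unname(tag_map[rownames(hto)[tag_idx]])
  }

  margin <- apply(clr, 2, function(x) {
    s <- sort(x, decreasing = TRUE)
    if (length(s) >= 2) s[1] - s[2] else s[1]
  })

  out <- data.frame(cell = colnames(hto), label = label,
                    margin = unname(margin), stringsAsFactors = FALSE)
  attr(out, "positive") <- positive
  class(out) <- c("hto_calls", "data.frame")
  out
}
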