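#' Graph-based clustering of nuclei
#'
#' Standard single-cell clustering: the (optionally HVG-restricted)
#' normalized matrix is gene-wise z-scaled (clipped at 10), reduced by PCA,
#' a shared-nearest-neighbor graph is built from the `n_neighbors` nearest
#' cells in PC space with Jaccard edge weights, and communities are found
#' by modularity (Louvain) optimization at the given resolution.
#'
#' @param normalized A [normalize_log()] result or a genes x cells matrix.
#' @param hvg Optional gene subset to cluster on.
#' @param n_pcs Principal components to retain (default 50; reduced with a
#'   warning when fewer are available).
#' @param n_neighbors Neighbors for the SNN graph (default 30).
#' @param resolution Modularity resolution (default 1.0).
#' @param seed Seed for the community detection.
#' @return Integer vector of cluster labels, contiguous from 0, named by
#'   cell.
#' @export
cluster_cells <- function(normalized, hvg = NULL, n_pcs = 50,
                          n_neighbors = 30, resolution = 1.0, seed = 1L) {
  mat <- if (inherits(normalized, "normalized_matrix")) normalized$mat
         else normalized
  if (!is.null(hvg)) mat <- mat[intersect(hvg, rownames(mat)), , drop = FALSE]
  n <- ncol(mat)
  if (n < n_neighbors + 1) {
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " cells")
  }
  x <- as.matrix(mat)
  mu <- rowMeans(x)
  sd_g <- apply(x, 1, sd)
  keep <- sd_g > 0
  x <- (x[keep, , drop = FALSE] - mu[keep]) / sd_g[keep]
  x[x > 10] <- 10
  x[x < -10] <- -10

  max_pcs <- min(nrow(x), n - 1)
  if (n_pcs > max_pcs) {
    warning("reducing n_pcs from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  pcs <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = n_pcs)$x

  k <- min(n_neighbors, n - 1)
  d2 <- as.matrix(stats::dist(pcs))
  nn <- apply(d2, 1, function(row) order(row)[2:(k + 1)])  # k x n
  nn_sets <- lapply(seq_len(n), function(i) c(i, nn[, i]))

  # SNN edges with Jaccard weights over neighbor sets
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (i in seq_len(n)) {
    for (j in nn[, i]) {
      if (j > i) {
        ov <- length(intersect(nn_sets[[i]], nn_sets[[j]]))
        w <- ov / (2 * (k + 1) - ov)
        if (w > 1 / 15) {
          ei <- c(ei, i); ej <- c(ej, j); ew <- c(ew, w)
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ei, to = ej, weight = ew),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comm <- with_seed(seed, {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  labels <- igraph::membership(comm)
  labels <- as.integer(factor(labels, levels = unique(labels[order(labels)])))
  setNames(labels - 1L, colnames(mat))
}

#' Assign major cell types to clusters from marker programs
#'
#' For each cluster and candidate type, scores the type as the mean (over
#' that type's markers present in the data) of the cluster's average
#' normalized expression minus the gene's global average; the cluster is
#' labeled with the arg-max type, or `"UNRESOLVED"` on a tie.
#'
#' @param normalized A [normalize_log()] result or genes x cells matrix.
#' @param clusters Cluster labels as returned by [cluster_cells()].
#' @param markers Named list: cell type -> marker gene ids.
#' @return Named character vector: cluster id -> cell type. The score
#'   matrix (types x clusters) is attached as attribute `scores`.
#' @export
score_markers <- function(normalized, clusters, markers) {
  mat <- if (inherits(normalized, "normalized_matrix")) normalized$mat
         else normalized
  stopifnot(length(clusters) == ncol(mat))
  present <- lapply(markers, intersect, rownames(mat))
  usable <- lengths(present) > 0
  if (!all(usable)) {
    warning("no markers present for type(s): ",
            paste(names(markers)[!usable], collapse = ", "))
  }
  present <- present[usable]
  if (length(present) == 0) stop("no marker genes found in the matrix")

  cl_levels <- sort(unique(clusters))
  global_mean <- Matrix::rowMeans(mat)
  scores <- matrix(0, nrow = length(present), ncol = length(cl_levels),
                   dimnames = list(names(present), as.character(cl_levels)))
  for (ci in seq_along(cl_levels)) {
    cl_mean <- Matrix::rowMeans(mat[, clusters == cl_levels[ci],
                                    drop = FALSE])
    for (ty in names(present)) {
      g <- present[[ty]]
      scores[ty, ci] <- mean(cl_mean[g] - global_mean[g])
    }
  }
  assignment <- apply(scores, 2, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1) "UNRESOLVED" else rownames(scores)[top]
  })
  attr(assignment, "scores") <- scores
  assignment
}

#' Expression-bin-matched module score
#'
#' Scores each cell for a gene set as the mean normalized expression of
#' the set genes minus the mean of expression-matched control genes: all
#' genes are binned into `n_bins` equal-frequency bins by average
#' expression, and `n_ctrl` control genes are drawn (with replacement,
#' seeded) from the bin of each set gene. Used for stemness scoring.
#'
#' @param normalized A [normalize_log()] result or genes x cells matrix.
#' @param gene_set Character vector of gene ids (intersected with the
#'   matrix features; empty intersection is an error).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Seed for the control draws.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(normalized, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1L) {
  mat <- if (inherits(normalized, "normalized_matrix")) normalized$mat
         else normalized
  gene_set <- intersect(gene_set, rownames(mat))
  if (length(gene_set) == 0) {
    stop("gene_set has no genes in common with the matrix")
  }
  avg <- Matrix::rowMeans(mat)
  n_bins <- min(n_bins, length(avg))
  # equal-frequency bins on average expression, ties spread by rank
  br <- quantile(rank(avg, ties.method = "first"),
                 probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(rank(avg, ties.method = "first"), breaks = br,
             include.lowest = TRUE, labels = FALSE)
  names(bin) <- names(avg)

  ctrl <- with_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  set_mean <- Matrix::colMeans(mat[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(mat[ctrl, , drop = FALSE])
  setNames(set_mean - ctrl_mean, colnames(mat))
}

#' Classical brain cell-type markers shipped with the package
#'
#' Reads the packaged marker table (cell type -> classical marker genes:
#' GFAP/AQP4 for astrocytes, FN1/COL4A1 for endothelium, CSF1R/PTPRC for
#' macrophage-microglia, RBFOX3/RELN for neurons and unipolar brush cells,
#' GAD2 for inhibitory neurons/interneurons, SOX2/CD44 for neural stem
#' cells, MOG/PLP1 for oligodendrocytes, PDGFRA for OPCs, VIM/NES/PAX6 for
#' radial glia, FAP for stroma, CD3E for T cells).
#'
#' @return Named list: cell type -> character vector of marker genes.
#' @export
brain_marker_table <- function() {
  path <- system.file("extdata", "brain_markers.csv", package = "snpool",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df$gene, df$celltype)
}

#' Stemness-associated gene list shipped with the package
#'
#' Classical stem-cell-associated markers used for per-nucleus stemness
#' module scores; any user gene list (e.g. from a GMT) may be used
#' instead.
#'
#' @return Character vector of gene symbols.
#' @export
stemness_genes <- function() {
  path <- system.file("extdata", "stemness.gmt", package = "snpool",
                      mustWork = TRUE)
  read_gmt(path)[["STEMNESS"]]
}
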