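#' Quasi-Poisson GLM for one gene
#'
#' Fits a log-link count regression by iteratively reweighted least
#' squares with a log size-factor offset, estimates the quasi-Poisson
#' dispersion \eqn{\hat\phi} as Pearson \eqn{\chi^2 /} residual df, and
#' tests the group coefficient with a Wald t-test whose standard error is
#' scaled by \eqn{\sqrt{\hat\phi}}. Non-convergence (or a degenerate fit)
#' flags the gene and returns p = 1.
#'
#' @param y Integer counts for one gene across cells.
#' @param group Factor whose first level is the referent; the coefficient
#'   reported is for the second level (natural-log fold change).
#' @param celltype Optional factor entering the model additively (the
#'   cell-type-adjusted model).
#' @param offset Per-cell log size factor (default 0).
#' @param max_iter IRLS iteration cap (default 50).
#' @return A list: `estimate`, `se`, `p`, `dispersion`, `df`, `converged`.
#' @export
fit_gene_glm <- function(y, group, celltype = NULL, offset = NULL,
                         max_iter = 50) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("`group` must have exactly 2 levels")
  if (any(table(group) < 2)) stop("need >= 2 cells per group level")
  n <- length(y)
  offset <- offset %||% rep(0, n)
  X <- if (is.null(celltype)) {
    stats::model.matrix(~group)
  } else {
    celltype <- droplevels(as.factor(celltype))
    stats::model.matrix(~ group + celltype)
  }
  coef_name <- paste0("group", levels(group)[2])

  fit <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson(link = "log"),
                     offset = offset,
                     control = list(maxit = max_iter))
    ),
    error = function(e) NULL
  )
  bad <- is.null(fit) || !fit$converged || fit$rank < ncol(X)
  if (bad) {
    return(list(estimate = NA_real_, se = NA_real_, p = 1,
                dispersion = NA_real_, df = NA_integer_, converged = FALSE))
  }
  mu <- fit$fitted.values
  df_resid <- n - fit$rank
  phi <- sum((y - mu)^2 / mu) / df_resid
  phi <- max(phi, 1e-8)
  # covariance of coefficients from the weighted QR, scaled by dispersion
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R)
  dimnames(cov_unscaled) <- list(colnames(X)[fit$qr$pivot],
                                 colnames(X)[fit$qr$pivot])
  est <- fit$coefficients[coef_name]
  se <- sqrt(phi * cov_unscaled[coef_name, coef_name])
  tval <- est / se
  list(
    estimate = unname(est),
    se = unname(se),
    p = unname(2 * pt(-abs(tval), df = df_resid)),
    dispersion = phi,
    df = df_resid,
    converged = TRUE
  )
}

#' Differential expression of each tumor type against non-tumor nuclei
#'
#' Per gene and tumor type, fits the quasi-Poisson GLM of
#' [fit_gene_glm()] on the cells of that tumor type together with all
#' referent (non-tumor) cells, with the log size factor as offset. The
#' adjusted model adds the major cell-type factor. P-values are
#' BH-adjusted within each (tumor type, model) family; a gene is
#' significant at adjusted p < `fdr`.
#'
#' @param counts Genes x cells count matrix.
#' @param group Per-cell group label (tumor types and the referent).
#' @param celltype Per-cell major cell type (required when
#'   `adjust = TRUE`).
#' @param adjust Include the cell-type factor (default `TRUE`).
#' @param referent Referent group label (default `"nontumor"`).
#' @param genes Genes to test (e.g. the top-4000 HVG list); default all.
#' @param size_factors Per-cell size factors (offset = log of these);
#'   default computed from column totals as in [normalize_log()].
#' @param fdr Significance threshold on adjusted p (default 0.05).
#' @return data.frame of class `de_results`: `gene`, `tumor_type`,
#'   `model`, `estimate`, `se`, `p`, `padj`, `direction`, `significant`.
#' @export
run_de <- function(counts, group, celltype = NULL, adjust = TRUE,
                   referent = "nontumor", genes = NULL,
                   size_factors = NULL, fdr = 0.05) {
  stopifnot(length(group) == ncol(counts))
  if (adjust && is.null(celltype)) {
    stop("`celltype` is required for the adjusted model")
  }
  if (!referent %in% group) stop("referent level '", referent, "' not found")
  genes <- genes %||% rownames(counts)
  stopifnot(all(genes %in% rownames(counts)))
  if (is.null(size_factors)) {
    total <- Matrix::colSums(counts)
    size_factors <- total / median(total)
  }
  offset_all <- log(size_factors)
  model_tag <- if (adjust) "adjusted" else "unadjusted"
  tumor_types <- setdiff(unique(group), referent)

  out <- list()
  for (tt in tumor_types) {
    sel <- group %in% c(referent, tt)
    if (sum(group == tt) < 50) {
      warning("tumor type '", tt, "' has fewer than 50 cells")
    }
    g2 <- factor(group[sel], levels = c(referent, tt))
    ct <- if (adjust) celltype[sel] else NULL
    off <- offset_all[sel]
    sub <- counts[genes, sel, drop = FALSE]
    res <- lapply(genes, function(gg) {
      f <- fit_gene_glm(as.numeric(sub[gg, ]), g2, celltype = ct,
                        offset = off)
      data.frame(gene = gg, tumor_type = tt, model = model_tag,
                 estimate = f$estimate, se = f$se, p = f$p,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$padj <- bh_adjust(res$p)
    res$direction <- ifelse(is.na(res$estimate) | res$estimate >= 0,
                            "up", "down")
    res$significant <- !is.na(res$padj) & res$padj < fdr
    out[[tt]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("de_results", "data.frame")
  out
}

#' Compare adjusted and unadjusted differential-expression results
#'
#' Per tumor type, partitions genes into significant-in-both,
#' adjusted-only and unadjusted-only sets, identifies sign-discordant
#' genes (significant in both models with opposite estimate signs), and
#' records the unadjusted/adjusted estimate ratio per gene.
#'
#' @param adjusted,unadjusted [run_de()] results over the same genes and
#'   tumor types.
#' @return A list of class `model_comparison`, one element per tumor
#'   type: `both`, `adjusted_only`, `unadjusted_only`, `discordant` (gene
#'   id vectors) and `estimate_ratio` (named numeric,
#'   unadjusted/adjusted).
#' @export
compare_models <- function(adjusted, unadjusted) {
  stopifnot(setequal(adjusted$gene, unadjusted$gene),
            setequal(adjusted$tumor_type, unadjusted$tumor_type))
  out <- list()
  for (tt in unique(adjusted$tumor_type)) {
    a <- adjusted[adjusted$tumor_type == tt, ]
    u <- unadjusted[unadjusted$tumor_type == tt, ]
    u <- u[match(a$gene, u$gene), ]
    sig_a <- a$gene[a$significant]
    sig_u <- u$gene[u$significant]
    both <- intersect(sig_a, sig_u)
    ia <- match(both, a$gene)
    iu <- match(both, u$gene)
    discordant <- both[sign(a$estimate[ia]) != sign(u$estimate[iu]) &
                         a$estimate[ia] != 0 & u$estimate[iu] != 0]
    ratio <- u$estimate / a$estimate
    names(ratio) <- a$gene
    out[[tt]] <- list(
      both = both,
      adjusted_only = setdiff(sig_a, sig_u),
      unadjusted_only = setdiff(sig_u, sig_a),
      discordant = discordant,
      estimate_ratio = ratio
    )
  }
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  for (tt in names(x)) {
    cat(tt, ": both ", length(x[[tt]]$both),
        ", adjusted-only ", length(x[[tt]]$adjusted_only),
        ", unadjusted-only ", length(x[[tt]]$unadjusted_only),
        ", sign-discordant ", length(x[[tt]]$discordant), "\n", sep = "")
  }
  invisible(x)
}
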