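#' Filter bulk variants for demultiplexing
#'
#' Keeps variants with total read depth of at least `min_depth`, allele
#' frequency (alt/total) of at least `min_af`, and alternate-allele depth
#' of at least `min_alt`. All bounds are inclusive ("at least").
#'
#' @param records data.frame with columns `snp`, `depth`, `alt` (numeric
#'   counts; `alt <= depth`).
#' @param min_depth Minimum total depth (default 10).
#' @param min_af Minimum allele frequency (default 0.05).
#' @param min_alt Minimum alternate-allele depth (default 5).
#' @return The kept subset of `records`, with an `af` column added.
#' @examples
#' filter_variants(data.frame(snp = c("a", "b"), depth = c(9, 100),
#'                            alt = c(5, 5)))
#' @export
filter_variants <- function(records, min_depth = 10, min_af = 0.05,
                            min_alt = 5) {
  stopifnot(all(c("snp", "depth", "alt") %in% names(records)),
            all(records$alt <= records$depth))
  records$af <- ifelse(records$depth > 0, records$alt / records$depth, 0)
  keep <- records$depth >= min_depth & records$af >= min_af &
    records$alt >= min_alt
  records[keep, , drop = FALSE]
}

#' Singlet log-likelihood of a cell's allele counts under one donor
#'
#' Sum over covered SNPs of the log binomial likelihood of the observed
#' alternate reads, \eqn{\ln \mathrm{Binom}(a_s; d_s, \mu_s)} with
#' \eqn{\mu_s = \epsilon + (1 - 2\epsilon) g_s} for donor dosage
#' \eqn{g_s \in \{0, 0.5, 1\}}. SNPs with missing genotype or zero depth
#' are skipped; the binomial coefficient is included (it is constant
#' across donors).
#'
#' @param ad,dp Numeric vectors of alternate and total read counts per SNP
#'   for one cell.
#' @param dosage Donor dosage vector aligned to `ad`/`dp` (NA = missing).
#' @param eps Allele error rate in (0, 0.5).
#' @return Log-likelihood (0 when no SNP is covered, with attribute
#'   `n_covered`).
#' @examples
#' singlet_loglik(ad = c(2, 0, 1), dp = c(2, 2, 2),
#'                dosage = c(1, 0, 0.5), eps = 0.01)
#' @export
singlet_loglik <- function(ad, dp, dosage, eps = 0.01) {
  stopifnot(eps > 0, eps < 0.5, length(ad) == length(dp),
            length(dosage) == length(dp))
  covered <- dp > 0 & !is.na(dosage)
  if (!any(covered)) {
    return(structure(0, n_covered = 0L))
  }
  mu <- eps + (1 - 2 * eps) * dosage[covered]
  structure(sum(dbinom(ad[covered], dp[covered], mu, log = TRUE)),
            n_covered = sum(covered))
}

#' Doublet log-likelihood under an unordered donor pair
#'
#' As [singlet_loglik()], with the per-SNP dosage replaced by the 50:50
#' mixture \eqn{(g_i + g_j)/2} of the two donors' dosages.
#'
#' @inheritParams singlet_loglik
#' @param dosage_i,dosage_j Dosage vectors of the two donors.
#' @return Log-likelihood; symmetric in the pair.
#' @export
doublet_loglik <- function(ad, dp, dosage_i, dosage_j, eps = 0.01) {
  singlet_loglik(ad, dp, (dosage_i + dosage_j) / 2, eps = eps)
}

#' Assign nuclei to donors from allele counts and known genotypes
#'
#' Evaluates, per cell, the binomial log-likelihood of every hypothesis:
#' K singlets (prior \eqn{(1-\delta)/K} each) and all \eqn{K(K-1)/2}
#' unordered doublet pairs (prior \eqn{\delta/\binom{K}{2}} each), with
#' doublet dosage the mean of the pair. Posteriors are the normalized
#' prior-weighted likelihoods. A cell is labeled with its top hypothesis
#' when the posterior reaches `tau`, otherwise `UNASSIGNED`; cells with no
#' covered SNP are `UNASSIGNED` with a uniform posterior.
#'
#' @param allele List with sparse matrices `ad` and `dp` (SNP x cells).
#' @param genotypes Donor x SNP dosage matrix (values 0/0.5/1, NA allowed).
#' @param eps Allele error rate (default 0.01).
#' @param delta Doublet prior (default 0.05).
#' @param tau Posterior threshold for a confident assignment (default 0.9).
#' @return A data.frame of class `genotype_calls` with columns `cell`,
#'   `label` (donor id, `"DOUBLET"` or `"UNASSIGNED"`), `best_singlet`,
#'   `doublet_pair`, `posterior`, `n_covered`; the full posterior matrix
#'   (hypotheses x cells) is attached as attribute `posterior_matrix`, the
#'   log-likelihoods as `loglik_matrix`.
#' @export
assign_genotype <- function(allele, genotypes, eps = 0.01, delta = 0.05,
                            tau = 0.9) {
  stopifnot(eps > 0, eps < 0.5, delta >= 0, delta < 1,
            tau > 0, tau <= 1, nrow(genotypes) >= 2)
  donors <- rownames(genotypes)
  K <- length(donors)
  snps <- rownames(allele$dp)
  stopifnot(!is.null(snps), all(snps %in% colnames(genotypes)))
  G <- genotypes[, snps, drop = FALSE]
  warn_indistinct_donors(G)

  pairs <- if (K >= 2) utils::combn(K, 2) else matrix(integer(), nrow = 2)
  hyp_names <- c(donors,
                 apply(pairs, 2, function(p) {
                   paste0("DBL:", donors[p[1]], "+", donors[p[2]])
                 }))
  log_prior <- c(rep(log((1 - delta) / K), K),
                 rep(log(delta / ncol(pairs)), ncol(pairs)))
  if (delta == 0) log_prior[-seq_len(K)] <- -Inf

  dp <- methods::as(allele$dp, "TsparseMatrix")
  n_cells <- ncol(dp)
  cells <- colnames(dp) %||% as.character(seq_len(n_cells))
  # triplets of covered entries
  ent_snp <- dp@i + 1L
  ent_cell <- dp@j + 1L
  ent_dp <- dp@x
  ad_dense <- as.matrix(allele$ad)
  ent_ad <- ad_dense[cbind(ent_snp, ent_cell)]

  n_hyp <- length(hyp_names)
  ll <- matrix(0, nrow = n_hyp, ncol = n_cells,
               dimnames = list(hyp_names, cells))
  dosage_for_hyp <- function(h) {
    if (h <= K) {
      G[h, ]
    } else {
      p <- pairs[, h - K]
      (G[p[1], ] + G[p[2], ]) / 2
    }
  }
  for (h in seq_len(n_hyp)) {
    dos <- dosage_for_hyp(h)[ent_snp]
    ok <- !is.na(dos) & ent_dp > 0
    mu <- eps + (1 - 2 * eps) * dos[ok]
    contrib <- dbinom(ent_ad[ok], ent_dp[ok], mu, log = TRUE)
    sums <- rowsum(contrib, group = ent_cell[ok])
    ll[h, as.integer(rownames(sums))] <- sums[, 1]
  }

  n_covered <- tabulate(ent_cell[ent_dp > 0], nbins = n_cells)
  log_post <- ll + log_prior
  post <- apply(log_post, 2, function(x) {
    if (all(!is.finite(x))) return(rep(1 / length(x), length(x)))
    exp(x - logsumexp(x))
  })
  post <- matrix(post, nrow = n_hyp, dimnames = list(hyp_names, cells))
  # uniform posterior for cells with no information
  post[, n_covered == 0] <- 1 / n_hyp

  best <- apply(post, 2, which.max)
  best_p <- post[cbind(best, seq_len(n_cells))]
  is_pair <- best > K
  label <- ifelse(is_pair, "DOUBLET", hyp_names[best])
  label[best_p < tau | n_covered == 0] <- "UNASSIGNED"

  out <- data.frame(
    cell = cells,
    label = label,
    best_singlet = donors[apply(post[seq_len(K), , drop = FALSE], 2,
                                which.max)],
    doublet_pair = ifelse(is_pair, hyp_names[best], NA_character_),
    posterior = unname(best_p),
    n_covered = n_covered,
    stringsAsFactors = FALSE
  )
  attr(out, "posterior_matrix") <- post
  attr(out, "loglik_matrix") <- ll
  attr(out, "params") <- list(eps = eps, delta = delta, tau = tau)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

warn_indistinct_donors <- function(G) {
  K <- nrow(G)
  if (K < 2) return(invisible())
  for (i in seq_len(K - 1)) {
    for (j in seq((i + 1), K)) {
      same <- G[i, ] == G[j, ]
      if (all(same | is.na(same))) {
        warning("donors ", rownames(G)[i], " and ", rownames(G)[j],
                " share every genotyped SNP; they cannot be separated")
      }
    }
  }
  invisible()
}
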