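#' Pipeline run configuration
#'
#' Collects every stage parameter in one validated place: the simulation
#' design, QC thresholds, HTO positive quantile, genotype-demux error
#' rate/doublet prior/assignment threshold, clustering parameters, the
#' enrichment FDR (0.1) and cell-type validation alpha (0.05), the DE
#' gene budget and FDR (0.05), and the master seed. Unknown keys are
#' rejected so a config file cannot silently misspell a parameter.
#'
#' @param simulate Named list of [sim_config()] arguments.
#' @param qc Named list of [qc_thresholds()] arguments.
#' @param hto Named list: `positive_quantile`.
#' @param genotype Named list: `eps`, `delta`, `tau`, `enabled`.
#' @param clustering Named list: `n_pcs`, `n_neighbors`, `resolution`.
#' @param enrichment Named list: `fdr`, `alpha`, `n_null_perms`.
#' @param de Named list: `n_hvg`, `fdr`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = list(), qc = list(), hto = list(),
                       genotype = list(), clustering = list(),
                       enrichment = list(), de = list(), seed = 1L) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      stop("unknown ", where, " config key(s): ", paste(bad, collapse = ", "))
    }
    x
  }
  sim_defaults <- list(n_samples_per_pool = 2, n_nuclei_per_sample = 400,
                       n_genes = 120, n_snps = 30, hto_stain_efficiency = 0.7)
  simulate <- utils::modifyList(
    sim_defaults,
    check_keys(simulate, names(formals(sim_config)), "simulate")
  )
  # demo default is scaled to the small simulated gene space; real data
  # would use the qc_thresholds() defaults (200 / 10,000 features)
  qc <- utils::modifyList(
    list(min_features = 20),
    check_keys(qc, names(formals(qc_thresholds)), "qc")
  )
  hto <- utils::modifyList(
    list(positive_quantile = 0.99),
    check_keys(hto, "positive_quantile", "hto")
  )
  genotype <- utils::modifyList(
    list(eps = 0.01, delta = 0.05, tau = 0.9, enabled = TRUE),
    check_keys(genotype, c("eps", "delta", "tau", "enabled"), "genotype")
  )
  clustering <- utils::modifyList(
    list(n_pcs = 50, n_neighbors = 30, resolution = 1.0),
    check_keys(clustering, c("n_pcs", "n_neighbors", "resolution"),
               "clustering")
  )
  enrichment <- utils::modifyList(
    list(fdr = 0.1, alpha = 0.05, n_null_perms = 50),
    check_keys(enrichment, c("fdr", "alpha", "n_null_perms"), "enrichment")
  )
  de <- utils::modifyList(
    list(n_hvg = 4000, fdr = 0.05),
    check_keys(de, c("n_hvg", "fdr"), "de")
  )
  structure(
    list(simulate = simulate, qc = qc, hto = hto, genotype = genotype,
         clustering = clustering, enrichment = enrichment, de = de,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, y)
}

#' Run the full pipeline on a simulated pool
#'
#' Executes simulate, preprocess (QC, normalization, HVG), HTO and
#' genotype demultiplexing, integration, annotation (clustering, marker
#' typing, stemness), single-cell enrichment with per-cluster
#' differential enrichment, adjusted and unadjusted differential
#' expression, and direction concordance, writing one schema-versioned
#' report per stage into `out_dir` plus a JSON log of per-stage counts
#' and seeds. Reruns with the same config are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (one run per directory).
#' @return Named list of report paths, invisibly; the log is also
#'   returned as attribute `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(schema_version = "1.0", seed = config$seed, stages = list())
  note <- function(stage, ...) {
    log$stages[[stage]] <<- list(...)
  }
  paths <- list()
  emit_csv <- function(name, df) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  emit_json <- function(name, x) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(c(list(schema_version = "1.0"), x), p,
                         auto_unbox = TRUE, digits = NA, na = "null")
    paths[[name]] <<- p
  }

  # simulate
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_pool(cfg)
  ds <- sim$dataset
  write_pool_dataset(sim, file.path(out_dir, "dataset"))
  paths[["dataset"]] <- file.path(out_dir, "dataset")
  note("simulate", n_cells = ncol(ds$counts), n_genes = nrow(ds$counts),
       seed = config$seed)

  # preprocess
  thr <- do.call(qc_thresholds, config$qc)
  keep <- qc_filter(ds$counts, ds$mito_genes, thr)
  counts <- ds$counts[, keep, drop = FALSE]
  norm <- normalize_log(counts)
  counts <- counts[, colnames(norm$mat), drop = FALSE]
  n_hvg <- min(config$de$n_hvg, nrow(counts))
  hvg <- select_hvg(counts, n_hvg)
  qc_report <- data.frame(
    cell = names(keep),
    n_features = Matrix::colSums(ds$counts > 0),
    total_counts = Matrix::colSums(ds$counts),
    kept = keep
  )
  emit_csv("qc_report", qc_report)
  note("preprocess", n_kept = ncol(counts), n_dropped = sum(!keep),
       n_hvg = n_hvg)

  cells <- colnames(counts)

  # HTO demux
  hto_calls <- classify_hto(ds$hto[, cells, drop = FALSE], ds$tag_map,
                            positive_quantile = config$hto$positive_quantile,
                            seed = config$seed + 1L)
  emit_csv("hto_calls", as.data.frame(hto_calls))
  note("demux_hto",
       n_singlet = sum(!(hto_calls$label %in% c("DOUBLET", "NEGATIVE"))),
       seed = config$seed + 1L)

  # genotype demux
  if (isTRUE(config$genotype$enabled)) {
    allele <- list(ad = ds$allele$ad[, cells, drop = FALSE],
                   dp = ds$allele$dp[, cells, drop = FALSE])
    gt_calls <- assign_genotype(allele, ds$genotypes,
                                eps = config$genotype$eps,
                                delta = config$genotype$delta,
                                tau = config$genotype$tau)
  } else {
    gt_calls <- data.frame(cell = cells, label = "UNASSIGNED",
                           best_singlet = NA_character_,
                           doublet_pair = NA_character_,
                           posterior = NA_real_, n_covered = 0L,
                           stringsAsFactors = FALSE)
  }
  emit_csv("genotype_calls", as.data.frame(gt_calls))
  note("demux_genotype", enabled = isTRUE(config$genotype$enabled),
       n_singlet = sum(!(gt_calls$label %in% c("DOUBLET", "UNASSIGNED"))))

  # integrate
  integrated <- integrate_calls(hto_calls, gt_calls)
  yield <- summarize_yield(integrated, hto_calls, gt_calls)
  emit_csv("integrated_calls", as.data.frame(integrated))
  emit_json("demux_summary", unclass(yield))
  note("integrate", n_kept = yield$n_integrated)

  kept <- integrated$cell[integrated$label != "DISCARDED"]
  sample_of <- setNames(integrated$label, integrated$cell)[kept]
  norm_kept <- norm$mat[, kept, drop = FALSE]
  counts_kept <- counts[, kept, drop = FALSE]

  # annotate
  clusters <- cluster_cells(norm_kept, hvg = hvg,
                            n_pcs = config$clustering$n_pcs,
                            n_neighbors = config$clustering$n_neighbors,
                            resolution = config$clustering$resolution,
                            seed = config$seed + 2L)
  type_of_cluster <- score_markers(norm_kept, clusters, ds$marker_table)
  stem <- module_score(norm_kept, stemness_genes_or_fallback(norm_kept),
                       seed = config$seed + 3L)
  annotation <- data.frame(
    cell = kept,
    sample = unname(sample_of),
    group = unname(ds$sample_groups[sample_of]),
    cluster = unname(clusters[kept]),
    celltype = unname(type_of_cluster[as.character(clusters[kept])]),
    stemness = unname(stem[kept])
  )
  emit_csv("annotation", annotation)
  note("annotate", n_clusters = length(unique(clusters)),
       seed = config$seed + 2L)

  # enrichment
  vam <- vam_scores(norm_kept, ds$gene_sets,
                    n_null_perms = config$enrichment$n_null_perms,
                    fdr_threshold = config$enrichment$fdr,
                    seed = config$seed + 4L)
  diff_enr <- differential_enrichment(vam$enriched, annotation$cluster,
                                      alpha = config$enrichment$alpha)
  emit_csv("enrichment_diff", as.data.frame(diff_enr))
  note("enrich", n_sets = ncol(vam$scores),
       n_significant = sum(diff_enr$significant), seed = config$seed + 4L)

  # differential expression (adjusted and unadjusted)
  referent <- "nontumor"
  de_possible <- referent %in% annotation$group &&
    length(setdiff(unique(annotation$group), referent)) >= 1
  if (de_possible) {
    sf <- norm$size_factors[kept]
    de_adj <- run_de(counts_kept, annotation$group, annotation$celltype,
                     adjust = TRUE, referent = referent, genes = hvg,
                     size_factors = sf, fdr = config$de$fdr)
    de_unadj <- run_de(counts_kept, annotation$group, NULL, adjust = FALSE,
                       referent = referent, genes = hvg,
                       size_factors = sf, fdr = config$de$fdr)
    de_all <- rbind(as.data.frame(de_adj), as.data.frame(de_unadj))
    emit_csv("de_results", de_all)
    note("de", n_genes = n_hvg,
         n_sig_adjusted = sum(de_adj$significant),
         n_sig_unadjusted = sum(de_unadj$significant))

    conc <- direction_concordance(de_adj)
    emit_json("concordance", unclass(conc))
    note("concord", n_all_types = conc$n_all)
  } else {
    emit_csv("de_results", data.frame())
    emit_json("concordance", list(note = "no tumor/referent contrast"))
    note("de", skipped = TRUE)
    note("concord", skipped = TRUE)
  }

  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(invisible(paths), log = log)
}

# packaged stemness list where its genes exist, else the most variable
# genes as a stand-in module (simulated features have synthetic names)
stemness_genes_or_fallback <- function(mat) {
  genes <- tryCatch(stemness_genes(), error = function(e) character(0))
  genes <- intersect(genes, rownames(mat))
  if (length(genes) >= 2) return(genes)
  v <- apply(as.matrix(mat), 1, var)
  head(names(sort(v, decreasing = TRUE)), 10)
}
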