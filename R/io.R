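#' Write a simulated pool to disk in standard formats
#'
#' Emits the expression matrix as MatrixMarket MTX with `barcodes.tsv` and
#' `features.tsv`, HTO counts as CSV (tags x cells plus the tag-to-sample
#' map), per-cell allele counts as long-format TSV (cell, snp, ref_count,
#' alt_count), the donor genotype table as TSV, sample metadata as CSV,
#' and the ground truth as JSON.
#'
#' @param sim A [simulate_pool()] result (`pool_sim`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pool_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pool_sim"))
  ds <- sim$dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(ds$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(ds$counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(ds$counts), file.path(dir, "features.tsv"))

  hto_df <- data.frame(tag = rownames(ds$hto), as.data.frame(ds$hto),
                       check.names = FALSE)
  write.csv(hto_df, file.path(dir, "hto_counts.csv"), row.names = FALSE)
  write.csv(data.frame(tag = names(ds$tag_map), sample = unname(ds$tag_map)),
            file.path(dir, "tag_map.csv"), row.names = FALSE)

  ad <- methods::as(ds$allele$ad, "TsparseMatrix")
  dp <- methods::as(ds$allele$dp, "TsparseMatrix")
  dp_long <- data.frame(
    cell = colnames(ds$allele$dp)[dp@j + 1L],
    snp = rownames(ds$allele$dp)[dp@i + 1L],
    depth = dp@x, stringsAsFactors = FALSE
  )
  ad_dense <- as.matrix(ds$allele$ad)
  alt <- ad_dense[cbind(match(dp_long$snp, rownames(ad_dense)),
                        match(dp_long$cell, colnames(ad_dense)))]
  allele_df <- data.frame(
    cell = dp_long$cell, snp = dp_long$snp,
    ref_count = dp_long$depth - alt, alt_count = alt
  )
  write.table(allele_df, file.path(dir, "allele_counts.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  geno_df <- data.frame(donor = rownames(ds$genotypes),
                        as.data.frame(ds$genotypes), check.names = FALSE)
  write.table(geno_df, file.path(dir, "genotypes.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  write.csv(data.frame(sample = ds$samples,
                       group = unname(ds$sample_groups[ds$samples])),
            file.path(dir, "samples.csv"), row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Read a pool dataset written by [write_pool_dataset()]
#'
#' @param dir Directory containing the files.
#' @return A `pool_sim`-shaped list with `dataset` and `truth` (truth is
#'   `NULL` when no truth.json is present, e.g. for real data laid out the
#'   same way).
#' @export
read_pool_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "features.tsv")),
                           readLines(file.path(dir, "barcodes.tsv")))
  hto_df <- read.csv(file.path(dir, "hto_counts.csv"), check.names = FALSE)
  hto <- as.matrix(hto_df[, -1, drop = FALSE])
  rownames(hto) <- hto_df$tag
  tm <- read.csv(file.path(dir, "tag_map.csv"))
  tag_map <- setNames(tm$sample, tm$tag)

  allele_df <- read.delim(file.path(dir, "allele_counts.tsv"))
  geno_df <- read.delim(file.path(dir, "genotypes.tsv"), check.names = FALSE)
  genotypes <- as.matrix(geno_df[, -1, drop = FALSE])
  rownames(genotypes) <- geno_df$donor
  snps <- colnames(genotypes)
  cells <- colnames(counts)
  i <- match(allele_df$snp, snps)
  j <- match(allele_df$cell, cells)
  dims <- c(length(snps), length(cells))
  allele <- list(
    ad = Matrix::sparseMatrix(i = i, j = j, x = allele_df$alt_count,
                              dims = dims, dimnames = list(snps, cells)),
    dp = Matrix::sparseMatrix(
      i = i, j = j, x = allele_df$alt_count + allele_df$ref_count,
      dims = dims, dimnames = list(snps, cells))
  )
  samp <- read.csv(file.path(dir, "samples.csv"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    t_df <- jsonlite::fromJSON(truth_path)
    class(t_df) <- c("sim_truth", "data.frame")
    t_df
  } else NULL

  dataset <- structure(
    list(counts = counts, hto = hto, tag_map = tag_map, allele = allele,
         genotypes = genotypes, samples = samp$sample,
         sample_groups = setNames(samp$group, samp$sample),
         mito_genes = rownames(counts)[grepl("^MT-", rownames(counts))],
         marker_table = NULL, gene_sets = NULL),
    class = "pool_dataset"
  )
  structure(list(dataset = dataset, truth = truth), class = "pool_sim")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t")[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read donor genotypes from a minimal VCF
#'
#' Parses the GT field of a VCF into a donor x SNP dosage matrix: `0/0`
#' (or `0|0`) is 0, heterozygous calls 0.5, `1/1` is 1, `./.` missing.
#' SNP ids are taken from the ID column (falling back to chrom:pos).
#'
#' @param path VCF path (uncompressed text).
#' @return Donor x SNP numeric dosage matrix.
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  stopifnot(length(header) > 9)
  donors <- header[-(1:9)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  gt_to_dosage <- function(gt) {
    gt <- sub(":.*", "", gt)
    alleles <- strsplit(gt, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    mean(as.numeric(alleles))
  }
  rows <- lapply(body, function(l) {
    f <- strsplit(l, "\t")[[1]]
    id <- if (f[3] %in% c(".", "")) paste0(f[1], ":", f[2]) else f[3]
    list(id = id,
         dosage = vapply(f[-(1:9)], gt_to_dosage, numeric(1),
                         USE.NAMES = FALSE))
  })
  m <- do.call(cbind, lapply(rows, `[[`, "dosage"))
  dimnames(m) <- list(donors, vapply(rows, `[[`, character(1), "id"))
  m
}
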