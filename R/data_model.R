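#' Construct a cohort genotype container
#'
#' Bundles an additive-coded dosage matrix (individuals in rows, variants in
#' columns, entries the number of minor alleles carried: 0, 1 or 2) with the
#' per-variant minor allele frequency (MAF) estimated from the loaded sample.
#' Columns whose coded allele is the major allele in this sample are flipped
#' (`g -> 2 - g`) so that every MAF is at most 0.5. Monomorphic variants are
#' retained with `maf = 0`; they contribute nothing to any downstream score.
#'
#' @param dosage numeric matrix, one row per individual, one column per
#'   variant, entries in \{0, 1, 2\}, no missing values.
#' @param sample_ids character vector of unique individual identifiers,
#'   one per row.
#' @param variant_ids character vector of unique variant identifiers,
#'   one per column.
#' @return An object of class `cohort_genotypes`: a list with elements
#'   `dosage`, `sample_ids`, `variant_ids` and `maf` (named per-variant
#'   minor allele frequency).
#' @export
cohort_genotypes <- function(dosage, sample_ids, variant_ids) {
  dosage <- as.matrix(dosage)
  if (length(sample_ids) != nrow(dosage))
    stop("sample_ids length does not match dosage rows", call. = FALSE)
  if (length(variant_ids) != ncol(dosage))
    stop("variant_ids length does not match dosage columns", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(variant_ids))
    stop("duplicate variant identifiers", call. = FALSE)
  if (anyNA(dosage))
    stop("dosage matrix contains missing values", call. = FALSE)
  if (!all(dosage %in% c(0, 1, 2)))
    stop("dosage entries must be 0, 1 or 2", call. = FALSE)
  storage.mode(dosage) <- "double"
  # orient to the minor allele in this sample
  n <- nrow(dosage)
  freq <- colSums(dosage) / (2 * n)
  flip <- freq > 0.5
  if (any(flip)) dosage[, flip] <- 2 - dosage[, flip]
  maf <- colSums(dosage) / (2 * n)
  dimnames(dosage) <- list(as.character(sample_ids), as.character(variant_ids))
  names(maf) <- as.character(variant_ids)
  structure(
    list(dosage = dosage,
         sample_ids = as.character(sample_ids),
         variant_ids = as.character(variant_ids),
         maf = maf,
         n_flipped = sum(flip)),
    class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", length(x$sample_ids), "individuals x",
      length(x$variant_ids), "variants\n")
  cat("  monomorphic:", sum(x$maf == 0),
      "| flipped to minor allele:", x$n_flipped, "\n")
  invisible(x)
}

#' Construct a gene map
#'
#' Assigns variants to genes. A variant may belong to at most one gene.
#'
#' @param map data.frame with columns `variant_id` and `gene_id`, or a named
#'   list of character vectors (gene id -> variant ids).
#' @param cohort optional `cohort_genotypes`; if given, every mapped variant
#'   must exist in the cohort.
#' @return Object of class `gene_map`: named list gene id -> variant ids.
#' @export
gene_map <- function(map, cohort = NULL) {
  if (is.data.frame(map)) {
    if (!all(c("variant_id", "gene_id") %in% names(map)))
      stop("gene map needs columns variant_id and gene_id", call. = FALSE)
    vid <- as.character(map$variant_id)
    gid <- as.character(map$gene_id)
  } else {
    gid <- rep(names(map), lengths(map))
    vid <- as.character(unlist(map, use.names = FALSE))
  }
  if (anyDuplicated(vid)) {
    dup <- unique(vid[duplicated(vid)])
    stop("variant(s) assigned to more than one gene: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cohort)) {
    missing <- setdiff(vid, cohort$variant_ids)
    if (length(missing))
      stop("gene map references variants absent from the cohort: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- split(vid, gid)
  # keep first-appearance gene order for reproducible iteration
  out <- out[unique(gid)]
  structure(out, class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat("gene_map:", length(x), "genes,", sum(lengths(x)), "variants\n")
  invisible(x)
}

#' Extract one gene's dosage block and MAFs
#'
#' @param cohort a `cohort_genotypes`.
#' @param map a `gene_map`.
#' @param gene gene identifier present in `map`.
#' @return list with `dosage` (n x m submatrix), `maf`, `variant_ids`.
#' @export
gene_block <- function(cohort, map, gene) {
  vids <- map[[gene]]
  if (is.null(vids)) stop("gene not in map: ", gene, call. = FALSE)
  list(dosage = cohort$dosage[, vids, drop = FALSE],
       maf = cohort$maf[vids],
       variant_ids = vids)
}

read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("genotype TSV needs a sample_id column plus >= 1 variant column: ",
         path, call. = FALSE)
  sample_ids <- as.character(df[[1]])
  g <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(g))
    stop("non-numeric genotype entries in ", path, call. = FALSE)
  n_missing <- sum(is.na(g))
  if (n_missing > 0) {
    message("imputing ", n_missing, " missing genotype(s) to 0 minor alleles")
    g[is.na(g)] <- 0
  }
  cohort_genotypes(g, sample_ids, colnames(df)[-1])
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi))
    stop("multi-allelic or ALT-less VCF record(s) at ",
         paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 5),
               collapse = ", "),
         "; only biallelic SNPs are supported", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  count_alt <- function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  g <- t(apply(gt, c(1, 2), function(s) {
    if (is.na(s)) NA_real_ else count_alt(s)
  }))
  n_missing <- sum(is.na(g))
  if (n_missing > 0) {
    message("imputing ", n_missing, " missing genotype(s) to 0 minor alleles")
    g[is.na(g)] <- 0
  }
  cohort_genotypes(g, colnames(gt), ids)
}

read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("phenotype TSV needs sample_id plus >= 1 replicate column: ",
         path, call. = FALSE)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("phenotype values must be finite numbers: ", path, call. = FALSE)
  df
}

#' Load genotypes, phenotypes and a gene map from files
#'
#' Reads a genotype source (VCF 4.x with GT fields, or a TSV matrix whose
#' header holds variant ids and whose first column holds sample ids), a
#' phenotype TSV (sample id plus one column per replicate) and a two-column
#' gene-map TSV (`variant_id`, `gene_id`). Samples are intersected and
#' reordered identically across all outputs (genotype order wins); alleles
#' are oriented so the coded allele is the minor allele in the loaded sample;
#' missing genotypes are imputed to 0 minor alleles with a message.
#'
#' @param genotype_source path to a `.vcf` file or a genotype TSV.
#' @param phenotype_path path to the phenotype TSV.
#' @param gene_map_path path to the gene-map TSV.
#' @return list with `cohort` (`cohort_genotypes`), `phenotypes` (data.frame,
#'   sample_id plus one numeric column per replicate, row order matching the
#'   cohort) and `map` (`gene_map`).
#' @export
load_cohort <- function(genotype_source, phenotype_path, gene_map_path) {
  for (p in c(genotype_source, phenotype_path, gene_map_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  cohort <- if (grepl("\\.vcf(\\.gz)?$", genotype_source))
    read_genotype_vcf(genotype_source) else read_genotype_tsv(genotype_source)
  phen <- read_phenotypes(phenotype_path)
  keep <- intersect(cohort$sample_ids, phen$sample_id)
  if (length(keep) == 0)
    stop("no overlapping samples between genotypes and phenotypes",
         call. = FALSE)
  if (length(keep) < length(cohort$sample_ids)) {
    idx <- match(keep, cohort$sample_ids)
    cohort <- cohort_genotypes(cohort$dosage[idx, , drop = FALSE],
                               keep, cohort$variant_ids)
  }
  phen <- phen[match(cohort$sample_ids, phen$sample_id), , drop = FALSE]
  rownames(phen) <- NULL
  mp <- utils::read.delim(gene_map_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  map <- gene_map(mp, cohort)
  list(cohort = cohort, phenotypes = phen, map = map)
}

result_columns <- c("gene_id", "method", "threshold", "statistic",
                    "p_raw", "p_corrected", "n_markers", "t_opt", "detail")

#' Assemble a per-gene test result table
#'
#' @param gene_id,method,threshold,statistic,p_raw,p_corrected,n_markers,t_opt,detail
#'   vectors, recycled to a common length. `method` is one of FT, WE, VT,
#'   CV_pmin, CV_lasso, COMB_pmin, COMB_lasso.
#' @return data.frame of class `gene_test_results` with one row per
#'   (gene, method).
#' @export
gene_test_results <- function(gene_id, method, threshold = NA_real_,
                              statistic = NA_real_, p_raw = NA_real_,
                              p_corrected = NA_real_, n_markers = NA_integer_,
                              t_opt = NA_real_, detail = NA_character_) {
  df <- data.frame(gene_id = as.character(gene_id),
                   method = as.character(method),
                   threshold = as.numeric(threshold),
                   statistic = as.numeric(statistic),
                   p_raw = as.numeric(p_raw),
                   p_corrected = as.numeric(p_corrected),
                   n_markers = as.integer(n_markers),
                   t_opt = as.numeric(t_opt),
                   detail = as.character(detail),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_test_results", "data.frame")
  df
}

#' Write a gene test result table to TSV
#'
#' Rows are sorted by (gene_id, method); numeric fields are written with 17
#' significant digits so that [read_results()] round-trips them exactly.
#'
#' @param results a `gene_test_results` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (nrow(results) == 0) stop("empty result set", call. = FALSE)
  results <- results[order(results$gene_id, results$method), , drop = FALSE]
  out <- results[, result_columns]
  for (col in c("threshold", "statistic", "p_raw", "p_corrected", "t_opt"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.17g", out[[col]]))
  ok <- tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a gene test result table written by [write_results()]
#'
#' @param path TSV path.
#' @return `gene_test_results` data.frame.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         method = "character",
                                         threshold = "numeric",
                                         statistic = "numeric",
                                         p_raw = "numeric",
                                         p_corrected = "numeric",
                                         n_markers = "integer",
                                         t_opt = "numeric",
                                         detail = "character"))
  class(df) <- c("gene_test_results", "data.frame")
  df
}
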