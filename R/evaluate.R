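#' Partition genes by variant MAF composition
#'
#' Splits genes into three groups at a 5% MAF threshold: group 1 holds
#' genes whose variants are all rare (every sample MAF < T), group 3 genes
#' whose variants are all common (every MAF >= T, boundary inclusive), and
#' group 2 the mixed genes with at least one variant on each side. Genes
#' with zero variants are excluded with a warning.
#'
#' @param cohort a `cohort_genotypes`.
#' @param map a `gene_map`.
#' @param threshold MAF split (default 0.05, independent of any analysis
#'   threshold).
#' @return Object of class `gene_partition`: list with `group1`, `group2`,
#'   `group3` (character gene ids) and `threshold`.
#' @export
partition_genes <- function(cohort, map, threshold = 0.05) {
  g1 <- character(0); g2 <- character(0); g3 <- character(0)
  empty <- character(0)
  for (g in names(map)) {
    mafs <- cohort$maf[map[[g]]]
    if (length(mafs) == 0) { empty <- c(empty, g); next }
    if (all(mafs < threshold)) g1 <- c(g1, g)
    else if (all(mafs >= threshold)) g3 <- c(g3, g)
    else g2 <- c(g2, g)
  }
  if (length(empty))
    warning(length(empty), " gene(s) with zero variants excluded")
  structure(list(group1 = g1, group2 = g2, group3 = g3,
                 threshold = threshold),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("gene_partition (T = %g): %d rare-only / %d mixed / %d common-only\n",
              x$threshold, length(x$group1), length(x$group2),
              length(x$group3)))
  invisible(x)
}

#' Power and type I error across replicates
#'
#' For each (method, threshold) family: power is the fraction of
#' causal-gene results detected across replicates, where detection means
#' corrected p below the Bonferroni level `alpha / N` with N the number of
#' genes tested by that family (overridable); the type I error rate is the
#' per-test fraction of noncausal-gene results with corrected p below the
#' uncorrected `alpha`, mirroring the asymmetric convention of power after
#' multiplicity control versus a nominal per-gene error rate.
#'
#' @param results_list list of `gene_test_results`, one per replicate, with
#'   `p_corrected` filled in.
#' @param truth character vector of causal gene ids (may be empty for a
#'   null experiment).
#' @param alpha significance level (default 0.05).
#' @param bonferroni_n optional Bonferroni denominator; default is the
#'   number of genes tested by the family.
#' @return data.frame with one row per family: method, threshold, power,
#'   type1, n_causal, n_noncausal, n_replicates, n_genes.
#' @export
estimate_power_type1 <- function(results_list, truth, alpha = 0.05,
                                 bonferroni_n = NULL) {
  stopifnot(length(results_list) >= 1, alpha > 0, alpha < 1)
  all_res <- do.call(rbind, lapply(seq_along(results_list), function(i) {
    r <- results_list[[i]]; r$replicate <- i; r
  }))
  fam_key <- paste(all_res$method,
                   ifelse(is.na(all_res$threshold), "", all_res$threshold))
  out <- list()
  for (f in unique(fam_key)) {
    sub <- all_res[fam_key == f, , drop = FALSE]
    genes_by_rep <- split(sub$gene_id, sub$replicate)
    ref <- sort(genes_by_rep[[1]])
    if (!all(vapply(genes_by_rep, function(g) identical(sort(g), ref),
                    logical(1))))
      stop("inconsistent gene sets across replicates for family ", f,
           call. = FALSE)
    tr <- intersect(truth, ref)
    if (length(tr) < length(truth) && length(truth))
      warning("causal gene(s) not tested by family ", f, ": ",
              paste(setdiff(truth, ref), collapse = ", "))
    N <- if (is.null(bonferroni_n)) length(ref) else bonferroni_n
    is_causal <- sub$gene_id %in% tr
    n_rep <- length(genes_by_rep)
    power <- if (length(tr) == 0) NA_real_ else
      sum(sub$p_corrected[is_causal] < alpha / N) / (length(tr) * n_rep)
    type1 <- if (all(is_causal)) NA_real_ else
      mean(sub$p_corrected[!is_causal] < alpha)
    out[[length(out) + 1L]] <- data.frame(
      method = sub$method[1], threshold = sub$threshold[1],
      power = power, type1 = type1, n_causal = length(tr),
      n_noncausal = sum(!is_causal), n_replicates = n_rep,
      n_genes = length(ref), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Quantile-quantile table of a p-value family
#'
#' @param p numeric p-values in (0, 1].
#' @return data.frame with `expected` and `observed` -log10 p-value
#'   coordinates, ordered so the most significant pair comes last; expected
#'   quantiles are the midpoint positions `(k - 0.5) / N`.
#' @export
qq_table <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) stop("empty p-value family", call. = FALSE)
  n <- length(p)
  data.frame(expected = -log10(((n:1) - 0.5) / n),
             observed = -log10(sort(p, decreasing = TRUE)))
}

#' Ranks of designated causal genes in one replicate
#'
#' Ranks all genes of a single-method, single-replicate result table by
#' ascending corrected p-value (average ranks on ties) and reports the rank
#' and p-value of each causal gene; untested causal genes are reported
#' with NA.
#'
#' @param results `gene_test_results` for one method and one replicate.
#' @param truth character vector of causal gene ids.
#' @return data.frame: gene_id, p, rank.
#' @export
rank_causal_genes <- function(results, truth) {
  stopifnot(length(unique(results$method)) == 1)
  p <- results$p_corrected
  if (all(is.na(p))) p <- results$p_raw
  rk <- rank(p, ties.method = "average")
  idx <- match(truth, results$gene_id)
  data.frame(gene_id = truth,
             p = p[idx],
             rank = rk[idx],
             stringsAsFactors = FALSE)
}

#' Combined rare+common tests across mixed genes
#'
#' Builds the Fisher combination per gene from already-computed (and, in the
#' standard pipeline, genomic-control-corrected) component tables: the FT
#' result at the split threshold supplies the rare p, the common-variant
#' result the corrected common p. Only genes present in both tables are
#' combined.
#'
#' @param rare_results FT rows of a `gene_test_results` (one threshold).
#' @param common_results CV rows of a `gene_test_results` (one method).
#' @param genes optional gene subset (e.g. the mixed group).
#' @return `gene_test_results` with method COMB_pmin or COMB_lasso.
#' @export
combine_results <- function(rare_results, common_results, genes = NULL) {
  stopifnot(all(rare_results$method == "FT"),
            length(unique(common_results$method)) == 1)
  cv_method <- unique(common_results$method)
  label <- if (cv_method == "CV_pmin") "COMB_pmin" else "COMB_lasso"
  shared <- intersect(rare_results$gene_id, common_results$gene_id)
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) == 0) stop("no genes shared by the two families",
                                call. = FALSE)
  ri <- match(shared, rare_results$gene_id)
  ci <- match(shared, common_results$gene_id)
  p_rare <- rare_results$p_corrected[ri]
  if (all(is.na(p_rare))) p_rare <- rare_results$p_raw[ri]
  p_common <- common_results$p_corrected[ci]
  U <- -2 * (log(p_rare) + log(p_common))
  p_comb <- stats::pchisq(U, df = 4, lower.tail = FALSE)
  gene_test_results(shared, label,
                    threshold = rare_results$threshold[ri],
                    statistic = U, p_raw = p_comb, p_corrected = p_comb,
                    n_markers = rare_results$n_markers[ri] +
                      common_results$n_markers[ci],
                    t_opt = NA_real_,
                    detail = sprintf("p_rare=%g;p_common=%g",
                                     p_rare, p_common))
}
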