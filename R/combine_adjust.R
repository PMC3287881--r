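#' Fisher's method for combining p-values
#'
#' Forms `U = -2 sum(log p_i)` from n p-values of independent tests and
#' refers U to a chi-square distribution with 2n degrees of freedom. With a
#' single p-value the combination is the identity.
#'
#' @param p_list numeric vector of p-values, each in (0, 1].
#' @return Object of class `combined_result`: list with `p_components`,
#'   `U`, `df = 2n`, `p_comb`.
#' @export
fisher_combine <- function(p_list) {
  p <- as.numeric(p_list)
  if (length(p) < 1) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  U <- -2 * sum(log(p))
  structure(list(p_components = p, U = U, df = 2L * length(p),
                 p_comb = stats::pchisq(U, df = 2 * length(p),
                                        lower.tail = FALSE)),
            class = "combined_result")
}

#' Combined rare + common test for one mixed gene
#'
#' For a gene holding both rare and common variants, aggregates the FT
#' burden signal of the rare subset (sample MAF < T, permutation p-value)
#' with the corrected common-variant p-value (minimum-p or LASSO) of the
#' complementary subset (MAF >= T) via Fisher's method. The two subsets are
#' disjoint and exhaust the gene. Genes lacking either subset are not
#' eligible (NULL is returned).
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF.
#' @param y phenotype vector.
#' @param threshold rare/common MAF split T (default 0.05).
#' @param common_method `"pmin"` or `"lasso"`.
#' @param B permutations for the FT component.
#' @param seed integer seed for the permutation stream.
#' @return one-row data.frame (method COMB_pmin or COMB_lasso) or NULL.
#' @export
combined_gene_test <- function(dosage, maf, y, threshold = 0.05,
                               common_method = c("pmin", "lasso"),
                               B = 1000, seed = 1L) {
  common_method <- match.arg(common_method)
  has_rare <- any(maf < threshold)
  has_common <- any(maf >= threshold & maf > 0)
  if (!has_rare || !has_common) return(NULL)
  rare <- rare_gene_test(dosage, maf, y, method = "ft",
                         threshold = threshold, B = B, seed = seed)
  common <- if (common_method == "pmin")
    gene_minp(dosage, maf, y, threshold)
  else {
    sel <- lasso_cp_path(dosage, maf, y, threshold)
    if (is.null(sel)) NULL else
      gene_lasso_pvalue(sel, dosage, y, m_total = ncol(dosage))
  }
  if (is.null(common)) return(NULL)
  fc <- fisher_combine(c(rare$p_raw, common$p_corrected))
  data.frame(method = paste0("COMB_", common_method), threshold = threshold,
             statistic = fc$U, p_raw = fc$p_comb, p_corrected = fc$p_comb,
             n_markers = ncol(dosage), t_opt = NA_real_,
             detail = sprintf("p_rare=%g;p_common=%g",
                              rare$p_raw, common$p_corrected),
             stringsAsFactors = FALSE)
}

#' Mean-ratio genomic-control correction of a p-value family
#'
#' Maps each p-value to the 1-df chi-square statistic with that upper-tail
#' probability, estimates the inflation factor as the ratio of the mean
#' observed statistic to its null expectation (exactly 1 for a 1-df
#' chi-square), divides every statistic by lambda and maps back to
#' p-values. By default lambda is floored at 1 so a deflated family is
#' never made more significant.
#'
#' @param p numeric vector of raw p-values in (0, 1]; at least 2.
#' @param floor_lambda floor lambda at 1 (default TRUE).
#' @return list with `adjustment` (class `gc_adjustment`: `lambda`,
#'   `lambda_raw`, `n_tests`, `mean_chisq`, `floored`) and `p_corrected`.
#' @export
genomic_control <- function(p, floor_lambda = TRUE) {
  p <- as.numeric(p)
  if (length(p) < 2) stop("need a family of at least 2 p-values",
                          call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  x <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda_raw <- mean(x)
  lambda <- if (floor_lambda) max(1, lambda_raw) else lambda_raw
  p_corr <- stats::pchisq(x / lambda, df = 1, lower.tail = FALSE)
  list(adjustment = structure(list(lambda = lambda,
                                   lambda_raw = lambda_raw,
                                   n_tests = length(p),
                                   mean_chisq = lambda_raw,
                                   floored = floor_lambda &&
                                     lambda_raw < 1),
                              class = "gc_adjustment"),
       p_corrected = p_corr)
}

#' @export
print.gc_adjustment <- function(x, ...) {
  cat(sprintf("genomic control: lambda = %.3f (raw %.3f) over %d tests\n",
              x$lambda, x$lambda_raw, x$n_tests))
  invisible(x)
}

#' Apply genomic control within each method family of a result table
#'
#' Overwrites `p_corrected` with the genomic-control-corrected p-value,
#' correcting each (method, threshold) family separately. For methods whose
#' raw p is already marker-corrected (CV tests), the correction is applied
#' to the existing corrected p-value; for permutation tests it is applied
#' to the raw p-value.
#'
#' @param results `gene_test_results` for one replicate.
#' @param floor_lambda see [genomic_control()].
#' @return list with `results` (p_corrected updated) and `lambdas` (named
#'   per-family inflation factors).
#' @export
gc_correct_results <- function(results, floor_lambda = TRUE) {
  fam <- paste(results$method,
               ifelse(is.na(results$threshold), "", results$threshold))
  lambdas <- c()
  for (f in unique(fam)) {
    idx <- which(fam == f)
    if (length(idx) < 2) next
    base <- if (all(is.na(results$p_corrected[idx])))
      results$p_raw[idx] else results$p_corrected[idx]
    gcres <- genomic_control(base, floor_lambda = floor_lambda)
    results$p_corrected[idx] <- gcres$p_corrected
    lambdas[f] <- gcres$adjustment$lambda
  }
  list(results = results, lambdas = lambdas)
}
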