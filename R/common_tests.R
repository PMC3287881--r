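#' Single-SNP additive linear regression
#'
#' Ordinary least squares of the phenotype on one variant's minor-allele
#' dosage with an intercept; the two-sided p-value comes from the slope's t
#' statistic with n - 2 degrees of freedom. A monomorphic variant returns a
#' flagged degenerate result (slope 0, p 1) rather than an error.
#'
#' @param g dosage vector for one variant.
#' @param y phenotype vector.
#' @return list with `slope`, `se`, `t`, `p`, `monomorphic`.
#' @export
snp_regression <- function(g, y) {
  n <- length(y)
  stopifnot(length(g) == n, n >= 3)
  gc_ <- g - mean(g)
  sxx <- sum(gc_^2)
  if (sxx == 0)
    return(list(slope = 0, se = NA_real_, t = 0, p = 1, monomorphic = TRUE))
  yc <- y - mean(y)
  slope <- sum(gc_ * yc) / sxx
  rss <- sum((yc - slope * gc_)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se == 0) Inf * sign(slope) else slope / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(slope = slope, se = se, t = tval, p = p, monomorphic = FALSE)
}

# p-values of y-on-column OLS slope tests for all columns at once
snp_regression_pvalues <- function(dosage, y) {
  n <- length(y)
  mu <- colMeans(dosage)
  v <- colSums(dosage^2) / n - mu^2
  p <- rep(1, ncol(dosage))
  poly <- v > 0
  if (any(poly)) {
    Gs <- scale(dosage[, poly, drop = FALSE])
    yc <- y - mean(y)
    sy <- sqrt(sum(yc^2) / (n - 1))
    if (sy > 0) {
      r <- as.vector(crossprod(Gs, yc)) / ((n - 1) * sy)
      r2 <- pmin(r^2, 1 - 1e-15)
      tt <- sqrt(r2 * (n - 2) / (1 - r2))
      p[poly] <- 2 * stats::pt(-tt, df = n - 2)
    }
  }
  list(p = p, polymorphic = poly)
}

#' Per-gene minimum-p common-variant test
#'
#' Regresses the phenotype on every polymorphic variant with sample MAF at
#' or above the threshold (the complement of the FT rare set) and summarizes
#' the gene by the minimum single-SNP p-value, Bonferroni-corrected by the
#' number of markers actually tested.
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF.
#' @param y phenotype vector.
#' @param threshold common-variant MAF cutoff (inclusive; default 0.05).
#' @return one-row data.frame (method CV_pmin) or NULL when the gene has no
#'   eligible variant.
#' @export
gene_minp <- function(dosage, maf, y, threshold = 0.05) {
  elig <- which(maf >= threshold)
  if (length(elig) == 0) return(NULL)
  sub <- dosage[, elig, drop = FALSE]
  sc <- snp_regression_pvalues(sub, y)
  if (!any(sc$polymorphic)) return(NULL)
  pv <- sc$p[sc$polymorphic]
  m <- length(pv)
  pmin_ <- min(pv)
  data.frame(method = "CV_pmin", threshold = threshold, statistic = pmin_,
             p_raw = pmin_, p_corrected = min(1, m * pmin_),
             n_markers = m, t_opt = NA_real_, detail = NA_character_,
             stringsAsFactors = FALSE)
}

#' LASSO regularization path with Mallows' Cp model choice
#'
#' Fits the L1 path of the phenotype on the gene's common variants
#' (standardized to unit variance before penalization) and scores each
#' model on the path with the Cp analog
#' `Cp_k = RSS_k / sigma2 - n + 2 df_k`, where `df_k` is the number of
#' nonzero coefficients. `sigma2` is the residual mean square of the
#' unpenalized OLS fit on all eligible variants when that fit has positive
#' residual degrees of freedom, otherwise the smallest residual mean square
#' along the path (flagged). The selected model minimizes Cp; ties go to
#' the smaller df. The intercept-only model is always a candidate.
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF.
#' @param y phenotype vector.
#' @param threshold common-variant MAF cutoff (inclusive; default 0.05).
#' @return Object of class `lasso_selection`: list with `selected`
#'   (variant column names/indices, possibly empty), `cp`, `df`, `rss` along
#'   the path, `sigma2`, `sigma2_fallback`, `n_eligible`, `eligible`;
#'   or NULL when no eligible polymorphic variant exists.
#' @export
lasso_cp_path <- function(dosage, maf, y, threshold = 0.05) {
  n <- length(y)
  elig <- which(maf >= threshold)
  if (length(elig) == 0) return(NULL)
  X <- dosage[, elig, drop = FALSE]
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) return(NULL)
  vid <- if (!is.null(colnames(X))) colnames(X) else
    as.character(elig[keep])
  m <- ncol(X)
  Xs <- scale(X)
  tss <- sum((y - mean(y))^2)

  path_beta <- list(); path_rss <- numeric(0); path_df <- integer(0)
  # intercept-only model is candidate 0
  path_beta[[1]] <- rep(0, m); path_rss[1] <- tss; path_df[1] <- 0L
  if (m == 1) {
    fit <- stats::lm.fit(cbind(1, Xs), y)
    path_beta[[2]] <- fit$coefficients[2]
    path_rss[2] <- sum(fit$residuals^2)
    path_df[2] <- 1L
  } else {
    gfit <- glmnet::glmnet(Xs, y, family = "gaussian",
                           standardize = FALSE, intercept = TRUE,
                           nlambda = 100, lambda.min.ratio = 1e-4)
    beta <- as.matrix(gfit$beta)
    fitted <- cbind(1, Xs) %*% rbind(gfit$a0, beta)
    for (k in seq_len(ncol(beta))) {
      path_beta[[k + 1]] <- beta[, k]
      path_rss[k + 1] <- sum((y - fitted[, k])^2)
      path_df[k + 1] <- sum(beta[, k] != 0)
    }
  }

  sigma2_fallback <- FALSE
  if (m <= n - 2) {
    ols <- stats::lm.fit(cbind(1, Xs), y)
    rdf <- n - ols$rank
    sigma2 <- sum(ols$residuals^2) / rdf
  } else {
    sigma2 <- min(path_rss / pmax(n - 1 - path_df, 1))
    sigma2_fallback <- TRUE
  }
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps

  cp <- path_rss / sigma2 - n + 2 * path_df
  near <- which(cp <= min(cp) + 1e-10)
  best <- near[which.min(path_df[near])]
  selected <- vid[path_beta[[best]] != 0]
  structure(list(selected = selected, cp = cp, df = path_df,
                 rss = path_rss, beta = path_beta, sigma2 = sigma2,
                 sigma2_fallback = sigma2_fallback,
                 n_eligible = m, eligible = vid,
                 best_index = best),
            class = "lasso_selection")
}

#' Gene-level p-value for the minimum-Cp LASSO model
#'
#' Refits the selected variants by unpenalized OLS and takes the overall
#' F-test p-value of that fit against the intercept-only model; an empty
#' selection gives p = 1 by convention. The correction multiplies by the
#' total number of SNPs in the gene (all MAFs), a deliberately conservative
#' factor since the LASSO's effective degrees of freedom equal the nonzero
#' coefficient count, typically far fewer.
#'
#' @param selection a `lasso_selection` from [lasso_cp_path()], computed on
#'   the same data.
#' @param dosage the gene's full dosage submatrix (column names must cover
#'   the selected variants).
#' @param y phenotype vector.
#' @param m_total total number of SNPs in the gene.
#' @return one-row data.frame (method CV_lasso).
#' @export
gene_lasso_pvalue <- function(selection, dosage, y, m_total) {
  stopifnot(inherits(selection, "lasso_selection"))
  detail <- if (length(selection$selected))
    paste(selection$selected, collapse = ",") else "empty_model"
  if (length(selection$selected) == 0) {
    p_raw <- 1; fstat <- NA_real_
  } else {
    X <- dosage[, selection$selected, drop = FALSE]
    fit <- stats::lm(y ~ X)
    if (anyNA(stats::coef(fit)))
      detail <- paste0(detail, ";rank_deficient")
    fs <- summary(fit)$fstatistic
    if (is.null(fs)) { p_raw <- 1; fstat <- NA_real_ } else {
      fstat <- unname(fs[1])
      p_raw <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    }
  }
  data.frame(method = "CV_lasso", threshold = NA_real_, statistic = fstat,
             p_raw = unname(p_raw),
             p_corrected = min(1, m_total * unname(p_raw)),
             n_markers = selection$n_eligible, t_opt = NA_real_,
             detail = detail, stringsAsFactors = FALSE)
}

#' Common-variant tests across genes
#'
#' Runs the per-gene minimum-p and/or LASSO-Cp common-variant tests on every
#' gene that has at least one polymorphic variant with MAF at or above the
#' threshold; genes without one are skipped (counted in a message).
#'
#' @param cohort a `cohort_genotypes`.
#' @param map a `gene_map`.
#' @param y phenotype vector aligned with the cohort.
#' @param methods subset of c("pmin", "lasso").
#' @param threshold common-variant MAF cutoff (inclusive, default 0.05).
#' @param genes optional subset of gene ids.
#' @return `gene_test_results` data.frame.
#' @export
run_common_tests <- function(cohort, map, y, methods = c("pmin", "lasso"),
                             threshold = 0.05, genes = NULL) {
  if (is.null(genes)) genes <- names(map)
  out <- list(); skipped <- 0L
  for (g in genes) {
    blk <- gene_block(cohort, map, g)
    any_row <- FALSE
    if ("pmin" %in% methods) {
      row <- gene_minp(blk$dosage, blk$maf, y, threshold)
      if (!is.null(row)) {
        row$threshold <- threshold
        out[[length(out) + 1L]] <- cbind(gene_id = g, row,
                                         stringsAsFactors = FALSE)
        any_row <- TRUE
      }
    }
    if ("lasso" %in% methods) {
      sel <- lasso_cp_path(blk$dosage, blk$maf, y, threshold)
      if (!is.null(sel)) {
        row <- gene_lasso_pvalue(sel, blk$dosage, y,
                                 m_total = ncol(blk$dosage))
        row$threshold <- threshold
        out[[length(out) + 1L]] <- cbind(gene_id = g, row,
                                         stringsAsFactors = FALSE)
        any_row <- TRUE
      }
    }
    if (!any_row) skipped <- skipped + 1L
  }
  if (skipped > 0)
    message(skipped, " gene(s) had no eligible common variant; omitted")
  if (length(out) == 0)
    stop("no gene had an eligible common variant", call. = FALSE)
  res <- do.call(rbind, out)
  gene_test_results(res$gene_id, res$method, res$threshold, res$statistic,
                    res$p_raw, res$p_corrected, res$n_markers, res$t_opt,
                    res$detail)
}
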