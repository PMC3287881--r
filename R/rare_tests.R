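#' Fixed-threshold (FT) burden score
#'
#' Collapses a gene's variants with sample MAF strictly below a threshold
#' into an unweighted per-individual minor-allele count
#' `s_i = sum_{j: maf_j < T} g_ij`.
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF (length m).
#' @param threshold MAF threshold T in (0, 0.5]; variants enter with
#'   `maf < T` (strict).
#' @return Object of class `burden_score`: list with `score` (length n),
#'   `weights` (all 1), `included_variants` (column indices or names),
#'   `threshold`, and `empty` (TRUE when no variant qualifies; the score is
#'   then identically zero).
#' @export
ft_burden <- function(dosage, maf, threshold) {
  stopifnot(threshold > 0, threshold <= 0.5, ncol(dosage) == length(maf))
  keep <- which(maf < threshold)
  s <- if (length(keep)) rowSums(dosage[, keep, drop = FALSE])
       else numeric(nrow(dosage))
  structure(list(score = s,
                 weights = rep(1, length(keep)),
                 included_variants = if (!is.null(colnames(dosage)))
                   colnames(dosage)[keep] else keep,
                 threshold = threshold,
                 empty = length(keep) == 0),
            class = "burden_score")
}

#' Reference group for Madsen-Browning weights
#'
#' The weighted test estimates allele frequencies in "unaffected" subjects.
#' For a quantitative trait the default reference group is the individuals
#' with phenotype at or below the sample median (a dichotomized control
#' set); `"all"` uses the whole sample instead.
#'
#' @param y phenotype vector.
#' @param type `"low_half"` (default) or `"all"`.
#' @return logical vector marking reference individuals.
#' @export
we_reference_group <- function(y, type = c("low_half", "all")) {
  type <- match.arg(type)
  if (type == "all") rep(TRUE, length(y)) else y <= stats::median(y)
}

#' Madsen-Browning weighted (WE) burden score
#'
#' Uses every variant in the gene regardless of MAF. Each variant is
#' weighted by `w_j = sqrt(n_ref * q_j * (1 - q_j))` with the pseudocount
#' frequency estimate `q_j = (c_j + 1) / (2 n_ref + 2)`, where `c_j` is the
#' variant's minor-allele count in the reference group; the score is
#' `s_i = sum_j g_ij / w_j`.
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param reference logical vector (length n) marking the reference group;
#'   see [we_reference_group()].
#' @return `burden_score` with the weights used (`threshold = "all"`).
#' @export
we_burden <- function(dosage, reference) {
  stopifnot(is.logical(reference), length(reference) == nrow(dosage))
  n_ref <- sum(reference)
  if (n_ref == 0) stop("empty reference group", call. = FALSE)
  cj <- colSums(dosage[reference, , drop = FALSE])
  q <- (cj + 1) / (2 * n_ref + 2)
  w <- sqrt(n_ref * q * (1 - q))
  s <- as.vector(dosage %*% (1 / w))
  structure(list(score = s, weights = w,
                 included_variants = if (!is.null(colnames(dosage)))
                   colnames(dosage) else seq_len(ncol(dosage)),
                 threshold = "all", empty = ncol(dosage) == 0),
            class = "burden_score")
}

#' Burden-phenotype association statistic
#'
#' Pearson correlation between a collapsed burden score and the phenotype;
#' defined as 0 when either is constant. Scale-free, so the statistic is
#' invariant to shifting y or rescaling y by a positive factor, and its
#' permutation ordering matches that of the usual burden score statistic.
#'
#' @param score a `burden_score` or numeric vector.
#' @param y phenotype vector of matching length.
#' @return correlation in [-1, 1].
#' @export
burden_statistic <- function(score, y) {
  s <- if (inherits(score, "burden_score")) score$score else score
  if (length(s) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(y) < 3) stop("need at least 3 individuals", call. = FALSE)
  sc <- s - mean(s); yc <- y - mean(y)
  den <- sqrt(sum(sc^2) * sum(yc^2))
  if (den == 0) return(0)
  sum(sc * yc) / den
}

#' Variable-threshold (VT) statistic
#'
#' Evaluates the absolute burden-phenotype correlation of the unweighted
#' collapse at every candidate threshold — the sorted distinct observed
#' MAFs of the gene's polymorphic variants, with inclusion `maf <= t` so
#' each variant enters at its own MAF — and returns the maximum, together
#' with the smallest maximizing threshold.
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF.
#' @param y phenotype vector.
#' @return list with `z_max`, `t_opt` (NA when degenerate), `thresholds`
#'   and `z_by_threshold`; `degenerate` is TRUE when no variant is
#'   polymorphic (then `z_max = 0`).
#' @export
vt_statistic <- function(dosage, maf, y) {
  cand <- sort(unique(maf[maf > 0]))
  if (length(cand) == 0)
    return(list(z_max = 0, t_opt = NA_real_, thresholds = numeric(0),
                z_by_threshold = numeric(0), degenerate = TRUE))
  z <- vapply(cand, function(t) {
    s <- rowSums(dosage[, maf <= t, drop = FALSE])
    abs(burden_statistic(s, y))
  }, numeric(1))
  best <- which.max(z)               # which.max returns the first maximum
  list(z_max = z[best], t_opt = cand[best], thresholds = cand,
       z_by_threshold = z, degenerate = FALSE)
}

#' Permutation p-value for a gene-level statistic
#'
#' Permutes the phenotype (genotypes fixed), recomputes the full statistic
#' for each permutation — for VT this repeats the threshold search — and
#' returns the estimator `p = (1 + #\{b: z_b >= z_obs\}) / (B + 1)`, which is
#' never zero and attains its floor `1/(B+1)` only when no permutation ties
#' or exceeds the observed value.
#'
#' @param statistic_fn function `(dosage, maf, y) -> scalar`; must return
#'   the already-absolute / maximized statistic.
#' @param dosage,maf gene block.
#' @param y phenotype vector.
#' @param B number of permutations (>= 1).
#' @param seed integer seed fixing the permutation stream.
#' @return list with `p_raw`, `statistic` (observed), `B`, `seed`.
#' @export
permutation_pvalue <- function(statistic_fn, dosage, maf, y, B = 1000,
                               seed = 1L) {
  stopifnot(B >= 1)
  z_obs <- statistic_fn(dosage, maf, y)
  set.seed(seed)
  n <- length(y)
  hits <- 0L
  for (b in seq_len(B)) {
    zb <- statistic_fn(dosage, maf, y[sample.int(n)])
    if (zb >= z_obs) hits <- hits + 1L
  }
  list(p_raw = (1 + hits) / (B + 1), statistic = z_obs, B = B, seed = seed)
}

# column-wise |correlation| of score columns S against phenotype columns Y.
# Returns K x C matrix; zero where either column is constant.
.abs_cor_cols <- function(S, Y) {
  Sc <- sweep(S, 2, colMeans(S))
  Yc <- sweep(Y, 2, colMeans(Y))
  sn <- sqrt(colSums(Sc^2))
  yn <- sqrt(colSums(Yc^2))
  num <- abs(crossprod(Sc, Yc))
  den <- outer(sn, yn)
  z <- num / den
  z[den == 0] <- 0
  z
}

# Shared-permutation engine: computes FT (possibly several thresholds), WE
# and VT statistics and permutation p-values for one gene from a single
# seed-derived permutation stream. Returns one row per requested method.
rare_tests_engine <- function(dosage, maf, y, methods, ft_thresholds,
                              B, seed, we_reference = "low_half") {
  n <- length(y)
  set.seed(seed)
  perms <- matrix(0L, n, B)
  for (b in seq_len(B)) perms[, b] <- sample.int(n)
  Y <- cbind(y, matrix(y[perms], n, B))
  # every column of Y is a permutation of y: mean and sum of squares are
  # shared, which saves full-matrix centering passes below
  ybar <- mean(y)
  yn <- sqrt(sum((y - ybar)^2))

  rows <- list()
  # static-score methods: FT at each threshold, VT cumulative columns
  S <- NULL; col_tag <- character(0)
  ft_info <- list()
  if ("ft" %in% methods) {
    for (Tt in ft_thresholds) {
      bs <- ft_burden(dosage, maf, Tt)
      S <- cbind(S, bs$score)
      col_tag <- c(col_tag, sprintf("ft_%g", Tt))
      ft_info[[sprintf("ft_%g", Tt)]] <-
        list(threshold = Tt, n_markers = length(bs$included_variants),
             empty = bs$empty)
    }
  }
  vt_cand <- numeric(0)
  if ("vt" %in% methods) {
    vt_cand <- sort(unique(maf[maf > 0]))
    for (t in vt_cand) {
      S <- cbind(S, rowSums(dosage[, maf <= t, drop = FALSE]))
      col_tag <- c(col_tag, sprintf("vt_%g", t))
    }
  }
  Z <- if (is.null(S)) matrix(0, 0, B + 1) else {
    Sc <- sweep(S, 2, colMeans(S))
    sn <- sqrt(colSums(Sc^2))
    den <- sn * yn
    zz <- abs(crossprod(Sc, Y)) / ifelse(den == 0, Inf, den)
    zz
  }

  pval <- function(zrow) (1 + sum(zrow[-1] >= zrow[1])) / (B + 1)

  if ("ft" %in% methods) {
    for (tag in names(ft_info)) {
      zrow <- Z[match(tag, col_tag), ]
      info <- ft_info[[tag]]
      rows[[length(rows) + 1L]] <- data.frame(
        method = "FT", threshold = info$threshold, statistic = unname(zrow[1]),
        p_raw = pval(zrow), n_markers = info$n_markers, t_opt = NA_real_,
        detail = if (info$empty) "empty_burden" else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if ("vt" %in% methods) {
    if (length(vt_cand) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = "VT", threshold = NA_real_, statistic = 0, p_raw = 1,
        n_markers = 0L, t_opt = NA_real_, detail = "degenerate",
        stringsAsFactors = FALSE)
    } else {
      idx <- grep("^vt_", col_tag)
      Zvt <- Z[idx, , drop = FALSE]
      zrow <- do.call(pmax, lapply(seq_len(nrow(Zvt)),
                                   function(i) Zvt[i, ]))
      best <- which.max(Zvt[, 1])
      rows[[length(rows) + 1L]] <- data.frame(
        method = "VT", threshold = NA_real_, statistic = unname(zrow[1]),
        p_raw = pval(zrow), n_markers = sum(maf > 0),
        t_opt = vt_cand[best], detail = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if ("we" %in% methods) {
    m <- ncol(dosage)
    if (we_reference == "all") {
      bs <- we_burden(dosage, rep(TRUE, n))
      zrow <- .abs_cor_cols(matrix(bs$score, ncol = 1), Y)[1, ]
    } else {
      # reference group (phenotype <= median) follows each permuted
      # phenotype, so the full statistic is recomputed per permutation;
      # the median and the reference-group size are permutation-invariant
      L <- (Y <= stats::median(y)) + 0
      n_ref <- sum(y <= stats::median(y))
      C <- crossprod(dosage, L)                   # m x (B+1) ref counts
      Q <- (C + 1) / (2 * n_ref + 2)
      W <- sqrt(n_ref * Q * (1 - Q))
      Sw <- dosage %*% (1 / W)                    # n x (B+1) scores
      msw <- colMeans(Sw)
      den <- sqrt(pmax(colSums(Sw^2) - n * msw^2, 0)) * yn
      num <- abs(colSums(Sw * Y) - n * msw * ybar)
      zrow <- num / ifelse(den == 0, Inf, den)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      method = "WE", threshold = NA_real_, statistic = unname(zrow[1]),
      p_raw = pval(zrow), n_markers = m, t_opt = NA_real_,
      detail = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Rare-variant collapsing test for one gene
#'
#' Runs the FT, WE or VT collapsing test on one gene block with an
#' empirical permutation p-value (phenotype permuted, genotypes fixed,
#' full statistic — including the VT threshold search and the WE reference
#' group — recomputed for every permutation).
#'
#' @param dosage n x m dosage submatrix for one gene.
#' @param maf per-variant sample MAF.
#' @param y phenotype vector.
#' @param method `"ft"`, `"we"` or `"vt"`.
#' @param threshold FT MAF threshold (default 0.05; ignored by WE/VT).
#' @param B permutations (default 1000).
#' @param seed integer seed.
#' @param we_reference `"low_half"` (phenotype at or below the median) or
#'   `"all"`.
#' @return one-row data.frame: method, threshold, statistic, p_raw,
#'   n_markers, t_opt, detail.
#' @export
rare_gene_test <- function(dosage, maf, y, method = c("ft", "we", "vt"),
                           threshold = 0.05, B = 1000, seed = 1L,
                           we_reference = c("low_half", "all")) {
  method <- match.arg(method)
  we_reference <- match.arg(we_reference)
  rare_tests_engine(dosage, maf, y, methods = method,
                    ft_thresholds = threshold, B = B, seed = seed,
                    we_reference = we_reference)
}

#' Rare-variant tests across genes
#'
#' Applies the requested collapsing tests to every gene (default: all genes
#' in the map). Within a gene all methods share one seed-derived
#' permutation stream; gene seeds are derived from `seed` and the gene's
#' position so results are reproducible gene-by-gene.
#'
#' @param cohort a `cohort_genotypes`.
#' @param map a `gene_map`.
#' @param y numeric phenotype vector aligned with the cohort.
#' @param methods subset of c("ft", "we", "vt").
#' @param ft_thresholds FT thresholds to run (default 0.05).
#' @param B permutations per gene.
#' @param seed base integer seed.
#' @param genes optional subset of gene ids.
#' @param we_reference see [rare_gene_test()].
#' @return `gene_test_results` data.frame.
#' @export
run_rare_tests <- function(cohort, map, y, methods = c("ft", "we", "vt"),
                           ft_thresholds = 0.05, B = 1000, seed = 1L,
                           genes = NULL, we_reference = "low_half") {
  if (is.null(genes)) genes <- names(map)
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    blk <- gene_block(cohort, map, genes[k])
    df <- rare_tests_engine(blk$dosage, blk$maf, y, methods,
                            ft_thresholds, B,
                            seed = gene_seed(seed, genes[k]),
                            we_reference = we_reference)
    df <- cbind(gene_id = genes[k], df, stringsAsFactors = FALSE)
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  gene_test_results(res$gene_id, res$method, res$threshold, res$statistic,
                    res$p_raw, p_corrected = NA_real_, res$n_markers,
                    res$t_opt, res$detail)
}

# deterministic 32-bit gene seed derived from a base seed and the gene id
gene_seed <- function(seed, gene_id) {
  h <- sum(utf8ToInt(gene_id) * seq_along(utf8ToInt(gene_id)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
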