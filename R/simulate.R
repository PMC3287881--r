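#' Specify a synthetic exome cohort design
#'
#' Describes a cohort that mimics the architecture of an exome association
#' panel: genes fall into three groups — rare-only (every variant has sample
#' MAF < 5%), mixed rare+common, and common-only — with group-specific SNP
#' counts per gene, a right-skewed rare-MAF distribution, and a
#' two-subpopulation ancestry structure whose allele-frequency divergence
#' plus a phenotype mean shift acts as a confounder.
#'
#' Per-gene SNP counts are `1 + Poisson` (shifted so every gene has at least
#' one variant; mixed genes start at 2 so both a rare and a common slot
#' exist) with means matching the group targets. Rare population MAFs are
#' drawn from a Beta distribution truncated to (0, 0.05) whose shape2 is
#' solved so the truncated mean equals `rare_maf_mean`; common MAFs are
#' uniform on `common_maf_range`. Each mixed-gene SNP is common with
#' probability `mixed_common_frac` (at least one of each kind is forced).
#' Subpopulation frequencies follow a Balding-Nichols model with divergence
#' `fst` around the ancestral frequency.
#'
#' @param n_individuals cohort size (default 697).
#' @param n_genes integer vector of length 3: genes in the rare-only, mixed
#'   and common-only groups (defaults 1732, 1142, 331).
#' @param snp_means mean SNPs per gene for the three groups
#'   (defaults 3.155, 16.336, 1.106).
#' @param rare_maf_mean target mean of the truncated rare-MAF distribution
#'   (default 0.006).
#' @param rare_maf_shape1 Beta shape1 of the rare-MAF model (default 0.8).
#' @param common_maf_range range of common population MAFs
#'   (default c(0.05, 0.45)).
#' @param mixed_common_frac probability that a mixed-gene SNP is common
#'   (default 0.12, chosen so the pooled mixed-group mean MAF is about 0.035).
#' @param n_subpops number of subpopulations (only 2 supported).
#' @param fst Balding-Nichols allele-frequency divergence between
#'   subpopulations (default 0.05; 0 gives identical subpopulations).
#' @param gamma phenotype shift per unit ancestry (confounder strength;
#'   default 0 = no confounding; see [calibrate_confounder()]).
#' @param noise_sd phenotype residual standard deviation (default 1).
#' @param seed integer seed fixing the whole cohort draw.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_individuals = 697,
                         n_genes = c(1732, 1142, 331),
                         snp_means = c(3.155, 16.336, 1.106),
                         rare_maf_mean = 0.006,
                         rare_maf_shape1 = 0.8,
                         common_maf_range = c(0.05, 0.45),
                         mixed_common_frac = 0.12,
                         n_subpops = 2,
                         fst = 0.05,
                         gamma = 0,
                         noise_sd = 1,
                         seed = 1L) {
  stopifnot(n_individuals >= 2, length(n_genes) == 3, all(n_genes >= 0),
            length(snp_means) == 3, all(snp_means >= 1),
            rare_maf_mean > 0, rare_maf_mean < 0.05,
            rare_maf_shape1 > 0,
            common_maf_range[1] >= 0.05, common_maf_range[2] <= 0.5,
            mixed_common_frac > 0, mixed_common_frac < 1,
            n_subpops == 2, fst >= 0, fst < 1, noise_sd >= 0)
  if (snp_means[2] < 2)
    stop("mixed-group genes need a mean of at least 2 SNPs", call. = FALSE)
  # solve Beta shape2 so the (0, 0.05)-truncated mean hits the target
  a <- rare_maf_shape1
  tmean <- function(b) (a / (a + b)) * stats::pbeta(0.05, a + 1, b) /
    stats::pbeta(0.05, a, b)
  shape2 <- stats::uniroot(function(b) tmean(b) - rare_maf_mean,
                           c(1, 1e5), tol = 1e-10)$root
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_genes = as.integer(n_genes),
         snp_means = snp_means,
         rare_maf_mean = rare_maf_mean,
         rare_maf_shape1 = rare_maf_shape1,
         rare_maf_shape2 = shape2,
         common_maf_range = common_maf_range,
         mixed_common_frac = mixed_common_frac,
         n_subpops = 2L,
         fst = fst,
         gamma = gamma,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "study_design")
}

#' Closed-form mean of the design's rare-MAF distribution
#'
#' Mean of the Beta(shape1, shape2) distribution truncated to (0, 0.05);
#' by construction of [study_design()] it equals `rare_maf_mean`.
#'
#' @param design a `study_design`.
#' @return numeric scalar.
#' @export
rare_maf_mean <- function(design) {
  a <- design$rare_maf_shape1; b <- design$rare_maf_shape2
  (a / (a + b)) * stats::pbeta(0.05, a + 1, b) / stats::pbeta(0.05, a, b)
}

#' Draw rare population MAFs from the design's truncated Beta model
#'
#' @param design a `study_design`.
#' @param n number of draws.
#' @return numeric vector in (0, 0.05).
#' @export
draw_rare_mafs <- function(design, n) {
  a <- design$rare_maf_shape1; b <- design$rare_maf_shape2
  # inverse-CDF sampling restricted to (0, 0.05)
  u <- stats::runif(n, 0, stats::pbeta(0.05, a, b))
  stats::qbeta(u, a, b)
}

draw_common_mafs <- function(design, n) {
  stats::runif(n, design$common_maf_range[1], design$common_maf_range[2])
}

# Balding-Nichols subpopulation frequencies around ancestral p0
bn_subpop_freqs <- function(p0, fst) {
  if (fst == 0) return(cbind(p0, p0, deparse.level = 0))
  k <- (1 - fst) / fst
  cbind(stats::rbeta(length(p0), p0 * k, (1 - p0) * k),
        stats::rbeta(length(p0), p0 * k, (1 - p0) * k))
}

#' Simulate a cohort of genotypes with ancestry structure
#'
#' Draws a cohort according to a [study_design()]: individuals are split
#' evenly into two subpopulations; each variant's subpopulation frequencies
#' diverge from an ancestral frequency under a Balding-Nichols model; each
#' genotype is two independent allele draws at the individual's
#' subpopulation frequency (Hardy-Weinberg within subpopulation, no linkage
#' disequilibrium). Variants drawn for the rare (common) side of a gene are
#' redrawn until their sample MAF falls below (at or above) 5%, so
#' [partition_genes()] on the output recovers the designed groups exactly.
#'
#' @param design a `study_design`.
#' @return list with `cohort` (`cohort_genotypes`), `map` (`gene_map`),
#'   `ancestry` (0/1 subpopulation label per individual), `gene_groups`
#'   (named group index 1/2/3 per gene) and `design`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  n <- design$n_individuals
  ng <- design$n_genes
  anc <- rep(c(0L, 1L), c(floor(n / 2), ceiling(n / 2)))

  # per-gene SNP counts: shifted Poisson keeps every gene non-empty
  sizes <- c(
    1L + stats::rpois(ng[1], design$snp_means[1] - 1),
    2L + stats::rpois(ng[2], design$snp_means[2] - 2),
    1L + stats::rpois(ng[3], design$snp_means[3] - 1))
  group_of_gene <- rep.int(1:3, ng)
  gene_ids <- sprintf("G%05d", seq_along(sizes))
  m <- sum(sizes)
  gene_of_variant <- rep.int(seq_along(sizes), sizes)
  variant_ids <- unlist(lapply(seq_along(sizes), function(i)
    sprintf("%s_v%02d", gene_ids[i], seq_len(sizes[i]))), use.names = FALSE)

  # rare/common label per variant
  vgroup <- group_of_gene[gene_of_variant]
  is_common <- logical(m)
  is_common[vgroup == 3] <- TRUE
  mixed_idx <- which(vgroup == 2)
  if (length(mixed_idx)) {
    is_common[mixed_idx] <-
      stats::runif(length(mixed_idx)) < design$mixed_common_frac
    # force at least one rare and one common slot per mixed gene
    for (gi in which(group_of_gene == 2)) {
      vi <- which(gene_of_variant == gi)
      lab <- is_common[vi]
      if (all(lab)) is_common[vi[1]] <- FALSE
      if (!any(is_common[vi])) is_common[vi[length(vi)]] <- TRUE
    }
  }

  draw_variant_cols <- function(idx) {
    p0 <- numeric(length(idx))
    p0[is_common[idx]] <- draw_common_mafs(design, sum(is_common[idx]))
    p0[!is_common[idx]] <- draw_rare_mafs(design, sum(!is_common[idx]))
    fr <- bn_subpop_freqs(p0, design$fst)
    pm <- rbind(fr[, 1], fr[, 2])        # 2 x m block
    pe <- pm[cbind(rep(anc + 1L, length(idx)),
                   rep(seq_along(idx), each = n))]
    matrix(stats::rbinom(n * length(idx), 2L, pe), nrow = n)
  }

  g <- draw_variant_cols(seq_len(m))
  # enforce the sample-MAF side of each variant's designed rare/common label
  for (attempt in 1:100) {
    f <- colMeans(g) / 2
    maf <- pmin(f, 1 - f)
    bad <- (is_common & maf < 0.05) | (!is_common & maf >= 0.05)
    if (!any(bad)) break
    g[, bad] <- draw_variant_cols(which(bad))
  }
  if (any(bad <- {f <- colMeans(g) / 2; maf <- pmin(f, 1 - f)
                  (is_common & maf < 0.05) | (!is_common & maf >= 0.05)})) {
    # deterministic fallback: mid-range common / very rare forced draws
    for (j in which(bad)) {
      p0 <- if (is_common[j]) 0.3 else 0.002
      fr <- bn_subpop_freqs(p0, design$fst)
      repeat {
        col <- stats::rbinom(n, 2L, c(fr[1], fr[2])[anc + 1L])
        fj <- mean(col) / 2; mj <- min(fj, 1 - fj)
        if ((is_common[j] && mj >= 0.05) || (!is_common[j] && mj < 0.05)) break
      }
      g[, j] <- col
    }
  }

  cohort <- cohort_genotypes(g, sprintf("ind%04d", seq_len(n)), variant_ids)
  map <- gene_map(data.frame(variant_id = variant_ids,
                             gene_id = gene_ids[gene_of_variant],
                             stringsAsFactors = FALSE), cohort)
  names(group_of_gene) <- gene_ids
  list(cohort = cohort, map = map, ancestry = anc,
       gene_groups = group_of_gene, design = design)
}

#' Define a causal model
#'
#' @param variants data.frame with columns `variant_id`, `gene_id`, `beta`
#'   (per-minor-allele trait increase; all betas must be positive so effect
#'   signs are consistent within genes, matching a burden-style
#'   architecture). May have zero rows (pure null).
#' @param map optional `gene_map` for consistency checking.
#' @return Object of class `causal_model`.
#' @export
causal_model <- function(variants, map = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "gene_id", "beta") %in% names(variants)))
  if (nrow(variants) && any(variants$beta <= 0))
    stop("causal effects must be positive", call. = FALSE)
  if (!is.null(map) && nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      vids <- map[[variants$gene_id[i]]]
      if (is.null(vids) || !(variants$variant_id[i] %in% vids))
        stop("causal variant ", variants$variant_id[i],
             " not in gene ", variants$gene_id[i], call. = FALSE)
    }
  }
  structure(variants, class = c("causal_model", "data.frame"))
}

#' Draw a default mixed-architecture causal model from a simulated cohort
#'
#' Picks causal genes in the rare-only and mixed groups (defaults 4 and 5),
#' gives each 1 to 11 causal variants with sample MAF inside
#' [0.0007, 0.165], and assigns every causal variant the same positive
#' effect.
#'
#' @param sim output of [simulate_cohort()].
#' @param n_rare_genes,n_mixed_genes causal genes per group (defaults 4, 5).
#' @param beta per-allele effect (default 0.5).
#' @param seed integer seed.
#' @return `causal_model`.
#' @export
default_causal_model <- function(sim, n_rare_genes = 4, n_mixed_genes = 5,
                                 beta = 0.5, seed = 1L) {
  set.seed(seed)
  maf <- sim$cohort$maf
  pick <- function(group, k) {
    cand <- names(sim$gene_groups)[sim$gene_groups == group]
    cand <- cand[vapply(cand, function(g) {
      v <- sim$map[[g]]
      sum(maf[v] >= 0.0007 & maf[v] <= 0.165) >= 1
    }, logical(1))]
    if (length(cand) < k)
      stop("not enough eligible genes in group ", group, call. = FALSE)
    sample(cand, k)
  }
  genes <- c(pick(1, n_rare_genes), pick(2, n_mixed_genes))
  rows <- lapply(genes, function(g) {
    v <- sim$map[[g]]
    elig <- v[maf[v] >= 0.0007 & maf[v] <= 0.165]
    k <- sample(seq_len(min(11, length(elig))), 1)
    data.frame(variant_id = sample(elig, k), gene_id = g, beta = beta,
               stringsAsFactors = FALSE)
  })
  causal_model(do.call(rbind, rows), sim$map)
}

#' Simulate quantitative phenotype replicates
#'
#' `y = X beta + gamma * ancestry + eps`, with `eps ~ N(0, noise_sd^2)`
#' redrawn per replicate and genotypes held fixed. With `causal = NULL` and
#' `gamma = 0` the trait is independent of every genotype (pure null); with
#' `gamma > 0` ancestry confounds every variant whose frequency differs
#' between subpopulations.
#'
#' @param cohort a `cohort_genotypes`.
#' @param causal a `causal_model` or NULL.
#' @param ancestry 0/1 subpopulation label per individual (NULL = all 0).
#' @param gamma confounder effect (phenotype shift per unit ancestry).
#' @param noise_sd residual standard deviation.
#' @param n_replicates number of phenotype replicates.
#' @param seed integer seed.
#' @return data.frame: `sample_id` plus numeric columns `rep_1 ... rep_R`.
#' @export
simulate_phenotype <- function(cohort, causal = NULL, ancestry = NULL,
                               gamma = 0, noise_sd = 1, n_replicates = 1,
                               seed = 1L) {
  n <- length(cohort$sample_ids)
  if (is.null(ancestry)) ancestry <- rep(0, n)
  stopifnot(length(ancestry) == n, n_replicates >= 1, noise_sd >= 0)
  base <- gamma * ancestry
  if (!is.null(causal) && nrow(causal)) {
    missing <- setdiff(causal$variant_id, cohort$variant_ids)
    if (length(missing))
      stop("causal variant(s) absent from cohort: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    base <- base +
      as.vector(cohort$dosage[, causal$variant_id, drop = FALSE] %*%
                  causal$beta)
  }
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * n_replicates, 0, noise_sd), nrow = n)
  y <- base + eps
  out <- data.frame(sample_id = cohort$sample_ids, y,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("rep_", seq_len(n_replicates)))
  out
}

# vectorized per-SNP marginal chi-square statistics (1 df, from the OLS
# slope t-test p-value) for a set of phenotype columns
snp_scan_chisq <- function(dosage, Y) {
  n <- nrow(dosage)
  mu <- colMeans(dosage)
  poly <- colMeans(dosage^2) - mu^2 > 0
  Gs <- scale(dosage[, poly, drop = FALSE])
  Ys <- scale(as.matrix(Y))
  r <- crossprod(Gs, Ys) / (n - 1)
  r2 <- pmin(r^2, 1 - 1e-12)
  tt <- sqrt(r2 * (n - 2) / (1 - r2))
  p <- 2 * stats::pt(-tt, df = n - 2)
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Calibrate the ancestry confounder strength
#'
#' Finds the phenotype shift `gamma` at which the mean-based genomic-control
#' inflation factor of per-SNP regression tests on a pure confounder trait
#' (no causal variants) reaches a target. Residual draws are held fixed
#' across candidate `gamma` values (common random numbers), making the
#' inflation a smooth increasing function that a root finder can bracket.
#'
#' @param cohort a `cohort_genotypes`.
#' @param ancestry 0/1 subpopulation labels.
#' @param target_lambda target inflation factor (default 2.3).
#' @param noise_sd residual standard deviation (default 1).
#' @param n_replicates phenotype replicates averaged over (default 3).
#' @param seed integer seed.
#' @param gamma_max initial upper bracket, extended as needed (default 2).
#' @return list with `gamma`, achieved `lambda`, and the target.
#' @export
calibrate_confounder <- function(cohort, ancestry, target_lambda = 2.3,
                                 noise_sd = 1, n_replicates = 3, seed = 1L,
                                 gamma_max = 2) {
  n <- length(cohort$sample_ids)
  set.seed(seed)
  eps <- matrix(stats::rnorm(n * n_replicates, 0, noise_sd), nrow = n)
  lam <- function(gamma) {
    Y <- gamma * ancestry + eps
    mean(snp_scan_chisq(cohort$dosage, Y))
  }
  f <- function(g) lam(g) - target_lambda
  hi <- gamma_max
  while (f(hi) < 0 && hi < 64) hi <- hi * 2
  if (f(hi) < 0)
    stop("cannot reach target inflation; increase fst or cohort size",
         call. = FALSE)
  root <- stats::uniroot(f, c(0, hi), tol = 1e-3)
  list(gamma = root$root, lambda = lam(root$root),
       target_lambda = target_lambda)
}
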