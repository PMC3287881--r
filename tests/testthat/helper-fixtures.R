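# shared fixtures and independent oracles

# small deterministic cohort: explicit dosage matrix in, cohort out
make_cohort <- function(dosage, sample_ids = NULL, variant_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(variant_ids)) {
    cn <- colnames(dosage)
    variant_ids <- if (!is.null(cn) && !anyDuplicated(cn) && all(cn != ""))
      cn else sprintf("v%02d", seq_len(ncol(dosage)))
  }
  cohort_genotypes(dosage, sample_ids, variant_ids)
}

# all n! permutations of 1..n, one per row (exhaustive oracle, n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# exact conditional permutation p-value by full enumeration
exact_perm_p <- function(statistic_fn, dosage, maf, y) {
  z_obs <- statistic_fn(dosage, maf, y)
  pm <- all_perms(length(y))
  z <- apply(pm, 1, function(ix) statistic_fn(dosage, maf, y[ix]))
  mean(z >= z_obs)
}

# brute-force VT oracle: enumerate candidate thresholds directly with cor()
vt_brute_force <- function(dosage, maf, y) {
  cand <- sort(unique(maf[maf > 0]))
  z <- sapply(cand, function(t) {
    s <- rowSums(dosage[, maf <= t, drop = FALSE])
    if (stats::sd(s) == 0 || stats::sd(y) == 0) 0 else abs(stats::cor(s, y))
  })
  list(z_max = max(z), t_opt = cand[which.max(z)])
}

# absolute burden correlation statistic for the generic permutation engine
ft_abs_stat <- function(threshold) {
  function(dosage, maf, y)
    abs(burden_statistic(ft_burden(dosage, maf, threshold), y))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
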