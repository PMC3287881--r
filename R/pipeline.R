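#' Default end-to-end pipeline configuration
#'
#' Nested list understood by [run_pipeline()]. Sections: `design`
#' (arguments of [study_design()]), `causal` (NULL for a pure null trait,
#' or arguments of [default_causal_model()]), `phenotype` (`gamma` — a
#' number, or `"calibrate"` to target `target_lambda` via
#' [calibrate_confounder()] — plus `noise_sd`, `n_replicates`, `seed`) and
#' `analysis` (`ft_thresholds`, `threshold` for the rare/common split and
#' the CV tests, `common_methods`, `B`, `seed`, `gc`, `alpha`).
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(design = list(),
       causal = NULL,
       phenotype = list(gamma = 0, target_lambda = 2.3, noise_sd = 1,
                        n_replicates = 1, seed = 1L),
       analysis = list(ft_thresholds = 0.05, threshold = 0.05,
                       common_methods = c("pmin", "lasso"),
                       B = 1000, seed = 1L, gc = TRUE, alpha = 0.05),
       out_dir = NULL)
}

merge_config <- function(user) {
  cfg <- default_pipeline_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && is.list(cfg[[sec]]))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

#' Run the full simulate-test-combine-evaluate pipeline
#'
#' Simulates a cohort, assigns a causal model (optional), draws phenotype
#' replicates, partitions genes at 5% MAF, runs the rare-variant tests on
#' the rare-only and mixed groups and the common-variant tests on the mixed
#' group, applies per-family genomic control within each replicate, builds
#' the combined rare+common tests on the mixed genes from the corrected
#' components, and summarizes power and type I error per group. Fully
#' seeded: re-running with the same configuration reproduces every output.
#'
#' @param config nested list as in [default_pipeline_config()]; missing
#'   entries take their defaults.
#' @return list with `report` (per-group power/type1 tables), `lambdas`
#'   (per-replicate per-family inflation factors), `results` (per-replicate
#'   corrected result tables), `results_raw` (pre-correction), `qq`
#'   (replicate-1 QQ tables per family, pre and post correction),
#'   `partition`, `causal`, `sim`, `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  an <- cfg$analysis

  sim <- do.call(study_design, cfg$design)
  sim <- simulate_cohort(sim)
  part <- partition_genes(sim$cohort, sim$map, 0.05)

  causal <- if (is.null(cfg$causal))
    causal_model(data.frame(variant_id = character(0),
                            gene_id = character(0), beta = numeric(0)))
  else do.call(default_causal_model, c(list(sim = sim), cfg$causal))

  gamma <- cfg$phenotype$gamma
  calib <- NULL
  if (identical(gamma, "calibrate")) {
    calib <- calibrate_confounder(sim$cohort, sim$ancestry,
                                  target_lambda = cfg$phenotype$target_lambda,
                                  noise_sd = cfg$phenotype$noise_sd,
                                  seed = cfg$phenotype$seed)
    gamma <- calib$gamma
  }
  phen <- simulate_phenotype(sim$cohort, causal, sim$ancestry,
                             gamma = gamma,
                             noise_sd = cfg$phenotype$noise_sd,
                             n_replicates = cfg$phenotype$n_replicates,
                             seed = cfg$phenotype$seed)

  rare_genes <- c(part$group1, part$group2)
  results <- list(); results_raw <- list(); lambdas <- list()
  for (r in seq_len(cfg$phenotype$n_replicates)) {
    y <- phen[[r + 1]]
    res <- run_rare_tests(sim$cohort, sim$map, y,
                          methods = c("ft", "we", "vt"),
                          ft_thresholds = an$ft_thresholds,
                          B = an$B, seed = an$seed + r,
                          genes = rare_genes)
    if (length(part$group2)) {
      cv <- run_common_tests(sim$cohort, sim$map, y,
                             methods = an$common_methods,
                             threshold = an$threshold,
                             genes = part$group2)
      res <- rbind(res, cv)
    }
    results_raw[[r]] <- res
    res$p_corrected[is.na(res$p_corrected)] <-
      res$p_raw[is.na(res$p_corrected)]
    if (isTRUE(an$gc)) {
      gcres <- gc_correct_results(res)
      res <- gcres$results
      lambdas[[r]] <- gcres$lambdas
    }
    # combined tests on mixed genes from (corrected) components
    if (length(part$group2)) {
      ft_rows <- res[res$method == "FT" &
                       res$threshold == an$threshold, , drop = FALSE]
      for (cm in an$common_methods) {
        lab <- if (cm == "pmin") "CV_pmin" else "CV_lasso"
        cv_rows <- res[res$method == lab, , drop = FALSE]
        if (nrow(cv_rows))
          res <- rbind(res, combine_results(ft_rows, cv_rows,
                                            genes = part$group2))
      }
    }
    results[[r]] <- res
  }

  causal_genes <- unique(causal$gene_id)
  report <- list()
  rare_methods_sel <- function(df) df$method %in% c("FT", "WE", "VT")
  g1 <- lapply(results, function(df)
    df[rare_methods_sel(df) & df$gene_id %in% part$group1, , drop = FALSE])
  if (nrow(g1[[1]]))
    report$group1 <- estimate_power_type1(
      g1, intersect(causal_genes, part$group1), alpha = an$alpha)
  if (length(part$group2)) {
    g2 <- lapply(results, function(df)
      df[df$gene_id %in% part$group2, , drop = FALSE])
    report$group2 <- estimate_power_type1(
      g2, intersect(causal_genes, part$group2), alpha = an$alpha)
  }

  qq <- list()
  fam <- paste(results_raw[[1]]$method,
               ifelse(is.na(results_raw[[1]]$threshold), "",
                      results_raw[[1]]$threshold))
  for (f in unique(fam)) {
    raw1 <- results_raw[[1]][fam == f, , drop = FALSE]
    base <- ifelse(is.na(raw1$p_corrected), raw1$p_raw, raw1$p_corrected)
    qq[[f]] <- list(pre = qq_table(base))
    corr1 <- results[[1]]
    cfam <- paste(corr1$method,
                  ifelse(is.na(corr1$threshold), "", corr1$threshold))
    if (any(cfam == f))
      qq[[f]]$post <- qq_table(corr1$p_corrected[cfam == f])
  }

  out <- list(report = report, lambdas = lambdas, results = results,
              results_raw = results_raw, qq = qq, partition = part,
              causal = causal, gamma = gamma, calibration = calib,
              sim = sim, config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(out$results))
    write_results(out$results[[r]],
                  file.path(dir, sprintf("results_rep%03d.tsv", r)))
  for (grp in names(out$report))
    utils::write.table(out$report[[grp]],
                       file.path(dir, paste0("report_", grp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (f in names(out$qq)) {
    tag <- gsub("[^A-Za-z0-9._-]", "_", f)
    utils::write.table(out$qq[[f]]$pre,
                       file.path(dir, paste0("qq_pre_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$qq[[f]]$post))
      utils::write.table(out$qq[[f]]$post,
                         file.path(dir, paste0("qq_post_", tag, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `<prefix>_genotypes.tsv` (sample_id plus one 0/1/2 column per
#' variant), `<prefix>_genotypes.vcf` (VCF 4.2, GT only), `<prefix>_
#' phenotypes.tsv`, `<prefix>_gene_map.tsv` and, when a causal model is
#' given, `<prefix>_truth.tsv`.
#'
#' @param sim output of [simulate_cohort()].
#' @param phenotypes data.frame from [simulate_phenotype()].
#' @param prefix output path prefix.
#' @param causal optional `causal_model`.
#' @return character vector of written paths, invisibly.
#' @export
write_cohort_files <- function(sim, phenotypes, prefix, causal = NULL) {
  cohort <- sim$cohort
  paths <- c(genotypes = paste0(prefix, "_genotypes.tsv"),
             vcf = paste0(prefix, "_genotypes.vcf"),
             phenotypes = paste0(prefix, "_phenotypes.tsv"),
             map = paste0(prefix, "_gene_map.tsv"))
  gdf <- data.frame(sample_id = cohort$sample_ids,
                    cohort$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_vcf(cohort, paths["vcf"])
  utils::write.table(phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mp <- data.frame(variant_id = unlist(sim$map, use.names = FALSE),
                   gene_id = rep(names(sim$map), lengths(sim$map)),
                   stringsAsFactors = FALSE)
  utils::write.table(mp, paths["map"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(causal) && nrow(causal)) {
    paths["truth"] <- paste0(prefix, "_truth.tsv")
    utils::write.table(as.data.frame(causal), paths["truth"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

write_vcf <- function(cohort, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=raremix",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", cohort$sample_ids),
                     collapse = "\t")), con)
  m <- length(cohort$variant_ids)
  gt <- matrix(gt_code[cohort$dosage + 1], nrow = nrow(cohort$dosage))
  lines <- vapply(seq_len(m), function(j)
    paste(c("1", j, cohort$variant_ids[j], "A", "C", ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t"), character(1))
  writeLines(lines, con)
  invisible(path)
}
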