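# File I/O, validation, summary tables and the end-to-end pipeline.

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    tpk_stop(sprintf("%s: missing required column(s): %s", file,
                     paste(missing, collapse = ", ")),
             "twinpk_missing_column")
  }
  invisible(df)
}

#' Read and validate a concentration table
#'
#' Requires columns `subject_id`, `pair_id`, `zygosity`, `occasion`,
#' `time_h`, `conc` (and optionally `blq`); rejects duplicated times within
#' a subject-occasion (naming the subject) and duplicated rows.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_concentration_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "pair_id", "zygosity", "occasion",
                      "time_h", "conc"), path)
  if (is.null(df$blq)) df$blq <- is.na(df$conc)
  key <- paste(df$subject_id, df$occasion, df$time_h)
  if (anyDuplicated(key)) {
    bad <- df$subject_id[duplicated(key)][1]
    tpk_stop(sprintf(
      "%s: duplicated/non-monotone sampling times for subject %s", path, bad),
      "twinpk_invalid_input")
  }
  df
}

#' Read and validate a genotype table
#' @param path CSV path.
#' @return validated data.frame (`subject_id`, `locus`, `allele_count`).
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "locus", "allele_count"), path)
  df
}

#' Read and validate a covariate table
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_covariate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "pair_id", "zygosity", "sex", "age",
                      "bmi"), path)
  df
}

#' Table-1-style PK summary by zygosity
#'
#' Mean, SD, median, min, max and max/min fold-range per parameter per
#' zygosity group.
#'
#' @param per_subject per-subject PK table (as from [nca_cohort()]).
#' @param parameters parameter columns to summarize.
#' @return long data.frame: zygosity, parameter, n, mean, sd, median, min,
#'   max, ratio_max_min.
#' @export
summarize_pk <- function(per_subject,
                         parameters = c("cl_f", "auc_inf", "auc_7h", "vz",
                                        "cmax", "tmax", "t_half")) {
  parameters <- intersect(parameters, names(per_subject))
  out <- list()
  for (z in unique(per_subject$zygosity)) {
    d <- per_subject[per_subject$zygosity == z, ]
    for (p in parameters) {
      x <- d[[p]][!is.na(d[[p]])]
      if (!length(x)) next
      out[[length(out) + 1L]] <- data.frame(
        zygosity = z, parameter = p, n = length(x),
        mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        median = stats::median(x), min = min(x), max = max(x),
        ratio_max_min = max(x) / min(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full twin-PK heritability pipeline
#'
#' Simulates (or accepts) a cohort, runs NCA per subject-occasion, averages
#' occasions, summarizes PK by zygosity, fits the ACE/ADE/AE/CE twin models
#' on clearance with AIC selection, computes within-pair correlations, the
#' rGC statistic for clearance, AUC, Cmax and tmax, genotype trend tests
#' with a Bonferroni threshold, and the covariate multiple regression.
#' Identical config and seed give identical reports.
#'
#' @param config a [sim_config()].
#' @param cohort optional pre-built cohort (list with the three tables); by
#'   default simulated from `config`.
#' @param models twin models to fit.
#' @param n_boot bootstrap replicates for component CIs (0 skips CIs).
#' @param n_resamples rGC sibling resamples.
#' @param alpha,n_tests Bonferroni inputs for the association stage.
#' @param out_dir optional output directory; when given, all result tables
#'   and a JSON report are written there.
#' @return object of class `study_report` (named list of result tables).
#' @export
run_pipeline <- function(config, cohort = NULL,
                         models = c("ACE", "ADE", "AE", "CE"),
                         n_boot = 200L, n_resamples = 50L,
                         alpha = 0.05, n_tests = 10L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      tpk_stop(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "twinpk_stage_failure")
    })
  }
  if (is.null(cohort)) cohort <- stage("simulate", simulate_cohort(config))

  nca <- stage("nca", nca_cohort(cohort$concentration_table, config$dose_mg))
  pk_summary <- stage("summary", summarize_pk(nca$per_subject))

  pairs <- stage("pairs",
                 twin_pairs_from_table(nca$per_subject, "cl_f"))
  fits <- stage("heritability", {
    fl <- lapply(models, function(m) fit_twin_model(pairs, m))
    names(fl) <- models
    fl
  })
  sat <- stage("heritability", fit_twin_model(pairs, "saturated"))
  best <- select_model(fits)
  model_table <- do.call(rbind, lapply(c(fits, list(saturated = sat)),
    function(f) data.frame(
      model = f$model, a2 = f$a2, d2 = f$d2, c2 = f$c2, e2 = f$e2,
      chi2 = f$chi2_vs_saturated, p = f$p_vs_saturated, aic = f$aic,
      stringsAsFactors = FALSE)))
  rownames(model_table) <- NULL
  cis <- if (n_boot > 0) stage("ci", component_confidence_intervals(
    best, pairs, n_boot = n_boot, seed = config$seed)) else NULL

  correlations <- stage("correlation", {
    do.call(rbind, lapply(c("MZ", "DZ"), function(z) {
      r <- pairwise_correlation(pairs, z)
      data.frame(zygosity = z, r = r$r, ci_low = r$ci[1], ci_high = r$ci[2],
                 n_pairs = r$n_pairs, p = r$p, stringsAsFactors = FALSE)
    }))
  })

  rgc_tab <- stage("rgc", {
    do.call(rbind, lapply(c("cl_f", "auc_inf", "cmax", "tmax"), function(p) {
      d <- data.frame(subject_id = nca$per_occasion$subject_id,
                      pair_id = nca$per_occasion$pair_id,
                      value = nca$per_occasion[[p]])
      r <- compute_rgc(d, n_resamples = n_resamples, seed = config$seed)
      data.frame(parameter = p, vb = r$vb, vw = r$vw, rgc = r$rgc,
                 ci_low = r$ci_95[1], ci_high = r$ci_95[2],
                 negative = r$rgc < 0, stringsAsFactors = FALSE)
    }))
  })

  assoc <- stage("association", {
    pheno <- nca$per_subject[, c("subject_id", "cl_f")]
    gt <- cohort$genotype_table
    loci <- setdiff(unique(gt$locus), default_zygosity_loci()$name)
    thr <- bonferroni_threshold(alpha, n_tests)
    do.call(rbind, lapply(loci, function(lc) {
      g <- gt[gt$locus == lc, ]
      m <- match(pheno$subject_id, g$subject_id)
      tt <- genotype_trend_test(pheno$cl_f, g$allele_count[m])
      data.frame(locus = lc, n_genotypes = nrow(tt$groups),
                 jt = tt$test$statistic, p = tt$test$p,
                 significant = !is.na(tt$test$p) & tt$test$p < thr,
                 stringsAsFactors = FALSE)
    }))
  })

  regression <- stage("regression", {
    cov <- cohort$covariate_table
    cov <- cbind(cov, diet_scores(cov))
    m <- match(nca$per_subject$subject_id, cov$subject_id)
    gt <- cohort$genotype_table
    g1236 <- gt[gt$locus == "MDR1_C1236T", ]
    factors <- data.frame(
      sex = cov$sex[m], age = cov$age[m], bmi = cov$bmi[m],
      protein_score = cov$protein_score[m],
      vegetable_score = cov$vegetable_score[m])
    if (nrow(g1236)) {
      factors$MDR1_C1236T <-
        g1236$allele_count[match(nca$per_subject$subject_id,
                                 g1236$subject_id)]
    }
    mr <- multiple_regression(nca$per_subject$cl_f, factors)
    list(per_factor = mr$per_factor, overall = mr$overall)
  })

  report <- structure(list(
    pk_summary = pk_summary,
    model_comparison = model_table,
    selected_model = best$model,
    component_ci = if (is.null(cis)) NULL else cis$ci,
    correlations = correlations,
    rgc = rgc_tab,
    association = assoc,
    regression = regression,
    nca = nca,
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(
                        utils::packageVersion("twinpk")))),
    class = "study_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a study report to disk
#'
#' Writes each result table as CSV plus `report.json` with the full report.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pk_summary, file.path(dir, "pk_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$model_comparison,
                   file.path(dir, "model_comparison.csv"), row.names = FALSE)
  utils::write.csv(report$rgc, file.path(dir, "rgc.csv"), row.names = FALSE)
  utils::write.csv(report$association, file.path(dir, "assoc.csv"),
                   row.names = FALSE)
  utils::write.csv(report$regression$per_factor,
                   file.path(dir, "regression.csv"), row.names = FALSE)
  utils::write.csv(report$nca$per_occasion,
                   file.path(dir, "pk_parameters.csv"), row.names = FALSE)
  keep <- setdiff(names(report), "nca")
  jsonlite::write_json(report[keep], file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Twin PK heritability study report\n")
  cat(sprintf("  selected twin model: %s\n", x$selected_model))
  cat(sprintf("  subjects analyzed: %d\n", nrow(x$nca$per_subject)))
  cat(sprintf("  config hash: %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  invisible(x)
}
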