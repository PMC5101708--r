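# Repeated-measures genetic component (Kalow):
#   rGC = (Vb - Vw) / Vb
# where Vw is the mean within-subject (occasion-to-occasion) variance and Vb
# the between-subject variance of the per-subject occasion means. Because the
# two siblings of a pair are not independent, the statistic is recomputed on
# random one-sibling-per-pair subsets and averaged.

#' The rGC statistic
#'
#' @param vb between-subject variance.
#' @param vw within-subject variance.
#' @return (vb - vw)/vb; may be negative when vw > vb (reported, never
#'   truncated).
#' @export
rgc_statistic <- function(vb, vw) {
  assert_that(vb > 0, "rGC is undefined for vb <= 0",
              class = "twinpk_degenerate_data")
  (vb - vw) / vb
}

#' Within- and between-subject variance of repeated measures
#'
#' `vw` is the mean over subjects of the per-subject sample variance
#' (denominator n_occasions - 1; subjects with fewer than 2 occasions are
#' excluded). `vb` is the sample variance (denominator n_subjects - 1) of
#' the per-subject occasion means; subjects with a single occasion still
#' contribute their value to `vb`.
#'
#' @param data data.frame with `subject_id` and `value` (one row per
#'   subject-occasion).
#' @param subjects optional subject_id subset.
#' @return list `vw`, `vb`, `n_subjects`, `n_subjects_vw`.
#' @export
within_between_variance <- function(data, subjects = NULL) {
  if (!is.null(subjects)) data <- data[data$subject_id %in% subjects, ]
  vals <- split(data$value, data$subject_id)
  means <- vapply(vals, mean, 0)
  vars <- vapply(vals, safe_var, 0)
  if (length(means) < 2 || sum(!is.na(vars)) < 2) {
    tpk_stop("need >= 2 subjects, >= 2 of them with >= 2 occasions",
             "twinpk_insufficient_data")
  }
  list(vw = mean(vars, na.rm = TRUE), vb = stats::var(means),
       n_subjects = length(means), n_subjects_vw = sum(!is.na(vars)))
}

#' Repeated-measures genetic component with random-sibling resampling
#'
#' For each replicate one sibling per pair is selected uniformly at random,
#' Vw and Vb are computed on that subset and rGC = (Vb - Vw)/Vb evaluated.
#' The point estimate is the mean of the replicate values; the 95% CI is the
#' 2.5/97.5 percentile of the replicate values. Replicates with Vb = 0 are
#' skipped and counted.
#'
#' @param data data.frame with `subject_id`, `pair_id`, `value` (one row per
#'   subject-occasion).
#' @param n_resamples replicates (50 by default).
#' @param seed RNG seed.
#' @param level CI level.
#' @return object of class `rgc_result`: `rgc`, `ci_95`, `vb`, `vw` (means
#'   over replicates), `per_resample`, `n_resamples`, `n_skipped`.
#' @export
compute_rgc <- function(data, n_resamples = 50L, seed = 1L, level = 0.95) {
  assert_that(all(c("subject_id", "pair_id", "value") %in% names(data)),
              "data needs columns subject_id, pair_id, value")
  subj <- unique(data[, c("subject_id", "pair_id")])
  sibs <- split(subj$subject_id, subj$pair_id)
  res <- with_seed(stream_seed(seed, "rgc"), {
    out <- data.frame(rgc = rep(NA_real_, n_resamples), vb = NA_real_,
                      vw = NA_real_)
    for (r in seq_len(n_resamples)) {
      pick <- vapply(sibs, function(s)
        if (length(s) == 1L) s else s[sample.int(length(s), 1L)], "")
      vv <- tryCatch(within_between_variance(data, pick),
                     twinpk_error = function(e) NULL)
      if (is.null(vv) || vv$vb <= 0) next
      out$vb[r] <- vv$vb; out$vw[r] <- vv$vw
      out$rgc[r] <- rgc_statistic(vv$vb, vv$vw)
    }
    out
  })
  ok <- !is.na(res$rgc)
  if (!any(ok)) tpk_stop("all resamples degenerate (vb = 0)",
                         "twinpk_degenerate_data")
  alpha <- (1 - level) / 2
  structure(list(
    rgc = mean(res$rgc[ok]),
    ci_95 = unname(stats::quantile(res$rgc[ok], c(alpha, 1 - alpha))),
    vb = mean(res$vb[ok]), vw = mean(res$vw[ok]),
    per_resample = res$rgc[ok],
    n_resamples = as.integer(n_resamples), n_skipped = sum(!ok)),
    class = "rgc_result")
}

#' @export
print.rgc_result <- function(x, ...) {
  cat(sprintf("rGC = %.3f (95%% CI %.3f-%.3f), Vb = %.4g, Vw = %.4g, %d resamples\n",
              x$rgc, x$ci_95[1], x$ci_95[2], x$vb, x$vw, x$n_resamples))
  invisible(x)
}
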