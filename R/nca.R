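# Non-compartmental analysis.
#
# Unit conventions (fixed throughout): dose mg, concentration ug/l, time h.
# AUC is reported in mg*min/l (ug*h/l x 0.06), clearance in l/min
# (dose / AUC_inf), Vz in l (= 60 * Cl/F / lambda_z).

UGH_TO_MGMIN <- 0.06  # ug*h/l -> mg*min/l

#' Construct a concentration-time profile
#'
#' Rows are sorted by time internally, so the row order of the input never
#' affects results. BLQ handling downstream: pre-peak BLQ values are treated
#' as 0, post-peak BLQ samples are excluded.
#'
#' @param times sampling times (h), first must be 0 after sorting.
#' @param conc concentrations (ug/l); `NA` allowed where `blq` is TRUE.
#' @param blq logical BLQ flags aligned to `times`.
#' @param dose_mg administered dose (mg).
#' @param subject_id,occasion identifiers carried into results.
#' @return object of class `concentration_profile`.
#' @export
concentration_profile <- function(times, conc, blq = rep(FALSE, length(times)),
                                  dose_mg, subject_id = NA_character_,
                                  occasion = NA_integer_) {
  assert_that(length(times) == length(conc) && length(times) == length(blq),
              "times, conc and blq must have equal length")
  ord <- order(times)
  times <- times[ord]; conc <- conc[ord]; blq <- as.logical(blq)[ord]
  assert_that(all(diff(times) > 0), sprintf(
    "duplicated or non-increasing sampling times for subject %s", subject_id))
  assert_that(times[1] == 0, "first sampling time must be 0 (pre-dose)")
  assert_that(dose_mg > 0, "dose must be positive")
  assert_that(all(conc[!blq & !is.na(conc)] >= 0),
              "concentrations must be non-negative")
  structure(list(times = times, conc = conc, blq = blq, dose_mg = dose_mg,
                 subject_id = subject_id, occasion = occasion),
            class = "concentration_profile")
}

# Resolve BLQ flags: pre-dose and pre-peak BLQ -> 0; post-peak BLQ excluded.
# Returns data.frame(t, c) of usable points (profile ends at the last
# quantifiable sample).
clean_profile <- function(profile) {
  t <- profile$times; c_ <- profile$conc; blq <- profile$blq
  quant <- !blq & !is.na(c_)
  if (!any(quant & t > 0)) {
    tpk_stop("no quantifiable post-dose concentrations (all BLQ)",
             "twinpk_insufficient_data")
  }
  i_max <- which(quant)[which.max(c_[quant])]
  keep <- quant | seq_along(t) <= i_max
  c_[blq | is.na(c_)] <- 0
  data.frame(t = t[keep], c = c_[keep])
}

#' Estimate the terminal elimination rate constant (lambda z)
#'
#' Log-linear least squares of ln(concentration) on time over trailing
#' windows of the post-peak points (the peak itself excluded). Every window
#' of the last k points, k = 3 up to all post-peak points, is fitted; the one
#' maximizing adjusted R-squared is selected, ties broken toward more points.
#'
#' @param profile a [concentration_profile()].
#' @return object of class `terminal_fit`: `lambda_z` (1/h),
#'   `intercept_log_conc` (ln ug/l at t = 0), `n_points_used`,
#'   `adjusted_r2`, `time_window` (h).
#' @export
estimate_lambda_z <- function(profile) {
  d <- clean_profile(profile)
  i_max <- which.max(d$c)
  cand <- d[-seq_len(i_max), , drop = FALSE]
  cand <- cand[cand$c > 0, , drop = FALSE]
  m <- nrow(cand)
  if (m < 3) {
    tpk_stop(sprintf("need >= 3 quantifiable post-peak points, have %d", m),
             "twinpk_insufficient_terminal_data")
  }
  best <- NULL
  for (k in 3:m) {
    w <- cand[(m - k + 1):m, ]
    f <- loglin_fit(w$t, w$c)
    if (is.null(best) || f$adj_r2 > best$adj_r2 + 1e-12 ||
        abs(f$adj_r2 - best$adj_r2) <= 1e-12) {  # ties -> larger k (later)
      best <- c(f, list(k = k, window = range(w$t)))
    }
  }
  lambda <- -best$slope
  if (!is.finite(lambda) || lambda <= 0) {
    tpk_stop("terminal regression slope is non-negative",
             "twinpk_nonpositive_slope")
  }
  structure(list(lambda_z = lambda, intercept_log_conc = best$intercept,
                 n_points_used = best$k, adjusted_r2 = best$adj_r2,
                 time_window = best$window),
            class = "terminal_fit")
}

# closed-form simple linear regression of log(c) on t
loglin_fit <- function(t, c_) {
  y <- log(c_)
  n <- length(t)
  tb <- mean(t); yb <- mean(y)
  sxx <- sum((t - tb)^2); sxy <- sum((t - tb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * tb
  ss_res <- sum((y - intercept - slope * t)^2)
  ss_tot <- sum((y - yb)^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# piecewise AUC of one interval, linear-up / log-down
interval_auc <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c1 > c2 && c1 > 0 && c2 > 0) {
    dt * (c1 - c2) / log(c1 / c2)
  } else {
    dt * (c1 + c2) / 2
  }
}

# concentration interpolated at time tt inside interval (linear on the rising
# limb, log-linear on the falling limb)
interp_conc <- function(t1, t2, c1, c2, tt) {
  if (c1 > c2 && c1 > 0 && c2 > 0) {
    exp(log(c1) + (log(c2) - log(c1)) * (tt - t1) / (t2 - t1))
  } else {
    c1 + (c2 - c1) * (tt - t1) / (t2 - t1)
  }
}

# internal AUC from 0 to t_end in ug*h/l on cleaned points
auc_partial_ughl <- function(d, t_end) {
  if (t_end > d$t[nrow(d)] + 1e-12) {
    tpk_stop(sprintf(
      "t_end = %g h is beyond the last quantifiable sample (%g h); %s",
      t_end, d$t[nrow(d)],
      "extrapolation is only available via auc_to_infinity"),
      "twinpk_extrapolation_required")
  }
  total <- 0
  for (i in seq_len(nrow(d) - 1L)) {
    t1 <- d$t[i]; t2 <- d$t[i + 1L]
    if (t_end <= t1 + 1e-12) break
    if (t_end >= t2 - 1e-12) {
      total <- total + interval_auc(t1, t2, d$c[i], d$c[i + 1L])
    } else {
      cc <- interp_conc(t1, t2, d$c[i], d$c[i + 1L], t_end)
      total <- total + interval_auc(t1, t_end, d$c[i], cc)
      break
    }
  }
  total
}

#' Partial AUC by the linear-up/log-down trapezoidal rule
#'
#' Linear trapezoid on intervals where concentration is non-decreasing (or
#' touches zero), logarithmic trapezoid \eqn{\Delta t (C_1-C_2)/\ln(C_1/C_2)}
#' where it is strictly decreasing and positive. When `t_end` falls between
#' samples the bounding concentration is interpolated (linear rising,
#' log-linear falling).
#'
#' @param profile a [concentration_profile()].
#' @param t_end upper limit (h); must not exceed the last quantifiable sample.
#' @return AUC from 0 to `t_end`, in mg*min/l.
#' @export
auc_partial <- function(profile, t_end) {
  assert_that(t_end > 0, "t_end must be positive")
  auc_partial_ughl(clean_profile(profile), t_end) * UGH_TO_MGMIN
}

#' AUC extrapolated to infinity
#'
#' \eqn{AUC_\infty = AUC_{0-t_{last}} + \hat C(t_{last})/\lambda_z}, where
#' \eqn{\hat C(t_{last})} is the concentration *predicted* by the terminal
#' regression at the last quantifiable time (not the observed value).
#'
#' @param profile a [concentration_profile()].
#' @param terminal_fit an [estimate_lambda_z()] result (fitted if missing).
#' @return list: `auc_inf` (mg*min/l), `auc_last` (mg*min/l),
#'   `extrapolated_fraction` (tail / AUC_inf).
#' @export
auc_to_infinity <- function(profile, terminal_fit = estimate_lambda_z(profile)) {
  d <- clean_profile(profile)
  t_last <- d$t[nrow(d)]
  auc_last <- auc_partial_ughl(d, t_last)
  c_hat <- exp(terminal_fit$intercept_log_conc -
                 terminal_fit$lambda_z * t_last)
  tail <- c_hat / terminal_fit$lambda_z
  auc_inf <- auc_last + tail
  list(auc_inf = auc_inf * UGH_TO_MGMIN,
       auc_last = auc_last * UGH_TO_MGMIN,
       extrapolated_fraction = tail / auc_inf)
}

#' Full non-compartmental parameter battery for one profile
#'
#' Assembles apparent clearance Cl/F = dose/AUC_inf (l/min), AUC_inf and
#' AUC over the first 7 h (mg*min/l), terminal half-life ln(2)/lambda_z (h),
#' Vz = dose/(lambda_z AUC_inf) (l), Cmax (ug/l) and tmax (h, earliest
#' maximum) as observed, and the extrapolated AUC fraction.
#'
#' @param profile a [concentration_profile()].
#' @param body_weight_kg optional body weight; adds `cl_f_per_kg` (ml/min/kg).
#' @return one-row data.frame of class `pk_parameters`.
#' @export
compute_pk_parameters <- function(profile, body_weight_kg = NULL) {
  d <- clean_profile(profile)
  if (sum(d$t > 0 & d$c > 0) < 4) {
    tpk_stop("fewer than 4 quantifiable post-dose points; full NCA needs >= 4",
             "twinpk_insufficient_data")
  }
  fit <- estimate_lambda_z(profile)
  aucs <- auc_to_infinity(profile, fit)
  i_max <- which.max(d$c)
  cl_f <- profile$dose_mg / aucs$auc_inf
  auc_7h <- if (d$t[nrow(d)] >= 7) auc_partial(profile, 7) else NA_real_
  out <- data.frame(
    subject_id = profile$subject_id, occasion = profile$occasion,
    cl_f = cl_f,
    cl_f_per_kg = if (is.null(body_weight_kg)) NA_real_ else
      1000 * cl_f / body_weight_kg,
    auc_inf = aucs$auc_inf, auc_7h = auc_7h,
    lambda_z = fit$lambda_z, t_half = log(2) / fit$lambda_z,
    vz = 60 * cl_f / fit$lambda_z,
    cmax = d$c[i_max], tmax = d$t[i_max],
    extrapolated_fraction = aucs$extrapolated_fraction,
    n_lambda_points = fit$n_points_used,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pk_parameters", "data.frame")
  out
}

#' Average PK parameters over occasions
#'
#' Per-subject arithmetic mean of each parameter over the available
#' occasions ("up to three study days").
#'
#' @param pk data.frame of per-occasion [compute_pk_parameters()] rows for
#'   one subject.
#' @return one-row data.frame with the occasion count in `n_occasions`.
#' @export
aggregate_occasions <- function(pk) {
  assert_that(nrow(pk) >= 1, "at least one occasion required")
  num <- vapply(pk, is.numeric, logical(1))
  num["occasion"] <- FALSE
  out <- pk[1, , drop = FALSE]
  out[num] <- lapply(pk[num], function(x) mean(x, na.rm = TRUE))
  out$occasion <- NULL
  out$n_occasions <- nrow(pk)
  rownames(out) <- NULL
  out
}

#' Run NCA over a cohort concentration table
#'
#' @param conc_table concentration table (schema of
#'   [simulate_concentration_profiles()]).
#' @param dose_mg administered dose (mg).
#' @param body_weights optional named vector (kg) by subject_id.
#' @return list: `per_occasion` (one row per subject-occasion),
#'   `per_subject` (occasion means, with pair/zygosity labels), `failures`
#'   (subject, occasion, message for profiles NCA could not process).
#' @export
nca_cohort <- function(conc_table, dose_mg, body_weights = NULL) {
  key <- interaction(conc_table$subject_id, conc_table$occasion, drop = TRUE)
  rows <- list(); fails <- list()
  for (grp in split(conc_table, key)) {
    prof <- concentration_profile(grp$time_h, grp$conc,
                                  grp$blq %||% is.na(grp$conc),
                                  dose_mg, grp$subject_id[1], grp$occasion[1])
    bw <- if (is.null(body_weights)) NULL else
      unname(body_weights[grp$subject_id[1]])
    res <- tryCatch(compute_pk_parameters(prof, bw),
                    twinpk_error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject_id = grp$subject_id[1], occasion = grp$occasion[1],
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      res$pair_id <- grp$pair_id[1]
      res$zygosity <- grp$zygosity[1]
      rows[[length(rows) + 1L]] <- res
    }
  }
  per_occ <- do.call(rbind, rows)
  per_occ <- per_occ[order(per_occ$subject_id, per_occ$occasion), ]
  rownames(per_occ) <- NULL
  per_subj <- do.call(rbind, lapply(split(per_occ, per_occ$subject_id),
                                    aggregate_occasions))
  per_subj <- per_subj[order(per_subj$subject_id), ]
  rownames(per_subj) <- NULL
  list(per_occasion = per_occ, per_subject = per_subj,
       failures = if (length(fails)) do.call(rbind, fails) else NULL)
}
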