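# Maximum-likelihood twin variance-component models.
#
# The classical twin design contrasts the within-pair covariance of MZ and DZ
# pairs. Under the path model, phenotypes of a pair are bivariate normal with
# common mean mu, variance a^2 + d^2 + c^2 + e^2 and covariance
#   a^2 + d^2 + c^2          (MZ)
#   a^2/2 + d^2/4 + c^2      (DZ).
# C and D are never co-estimated (not identifiable with twins only). The
# likelihood depends on the data only through per-zygosity sufficient
# statistics, so evaluation is O(1) in the number of pairs.

TWIN_MODELS <- c("ACE", "ADE", "AE", "CE", "E")
model_paths <- list(ACE = c("a", "c", "e"), ADE = c("a", "d", "e"),
                    AE = c("a", "e"), CE = c("c", "e"), E = "e")

#' Construct a twin pair set
#'
#' @param phenotype_sib1,phenotype_sib2 phenotype of each sibling.
#' @param zygosity character, "MZ" or "DZ" per pair.
#' @param label phenotype name (carried into outputs).
#' @return data.frame of class `twin_pairs`.
#' @export
twin_pairs <- function(phenotype_sib1, phenotype_sib2, zygosity,
                       label = "phenotype") {
  assert_that(length(phenotype_sib1) == length(phenotype_sib2) &&
                length(zygosity) == length(phenotype_sib1),
              "sibling phenotypes and zygosity must have equal length")
  assert_that(all(zygosity %in% c("MZ", "DZ")),
              "zygosity must be 'MZ' or 'DZ'")
  assert_that(!anyNA(phenotype_sib1) && !anyNA(phenotype_sib2),
              "missing phenotypes are not allowed within included pairs")
  out <- data.frame(x1 = phenotype_sib1, x2 = phenotype_sib2,
                    zygosity = zygosity, stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("twin_pairs", "data.frame")
  out
}

#' Build a twin pair set from a long phenotype table
#'
#' Siblings are ordered within pair by `subject_id` (canonical ordering, so
#' results never depend on input row order); multiple rows per subject
#' (occasions) are averaged first; pairs without exactly two non-missing
#' phenotypes are dropped.
#'
#' @param df data.frame with `subject_id`, `pair_id`, `zygosity` and the
#'   phenotype column.
#' @param column phenotype column name.
#' @return a [twin_pairs()] object.
#' @export
twin_pairs_from_table <- function(df, column) {
  assert_that(column %in% names(df), sprintf("missing column '%s'", column))
  df <- df[!is.na(df[[column]]), ]
  if (anyDuplicated(df$subject_id)) {
    df <- do.call(rbind, lapply(split(df, df$subject_id), function(s) {
      s[[column]][1] <- mean(s[[column]])
      s[1, , drop = FALSE]
    }))
  }
  df <- df[order(df$pair_id, df$subject_id), ]
  sp <- split(df, df$pair_id)
  if (!length(sp) || !any(vapply(sp, nrow, 0L) == 2L)) {
    tpk_stop("no complete twin pairs with non-missing phenotypes",
             "twinpk_insufficient_data")
  }
  sp <- sp[vapply(sp, nrow, 0L) == 2L]
  twin_pairs(vapply(sp, function(p) p[[column]][1], 0),
             vapply(sp, function(p) p[[column]][2], 0),
             vapply(sp, function(p) p$zygosity[1], ""),
             label = column)
}

# per-zygosity sufficient statistics: n, sum(x1+x2), sum(x1^2+x2^2), sum(x1 x2)
pair_suffstats <- function(pairs) {
  lapply(split(pairs, pairs$zygosity), function(d) {
    list(n = nrow(d), s1 = sum(d$x1 + d$x2), s2 = sum(d$x1^2 + d$x2^2),
         s12 = sum(d$x1 * d$x2))
  })
}

# log-likelihood of exchangeable bivariate normal(mu, sigma2, cov) given stats
biv_loglik <- function(st, mu, sigma2, cv) {
  det <- sigma2^2 - cv^2
  if (!is.finite(det) || det <= 0 || sigma2 <= 0) return(-Inf)
  qa <- st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2      # sum (x1-mu)^2+(x2-mu)^2
  qb <- st$s12 - mu * st$s1 + st$n * mu^2             # sum (x1-mu)(x2-mu)
  -st$n * log(2 * pi) - st$n / 2 * log(det) -
    (sigma2 * qa - 2 * cv * qb) / (2 * det)
}

# model-implied (sigma2, covMZ, covDZ) from squared paths
implied_cov <- function(a2, d2, c2, e2) {
  list(sigma2 = a2 + d2 + c2 + e2,
       mz = a2 + d2 + c2,
       dz = 0.5 * a2 + 0.25 * d2 + c2)
}

#' Twin-model log-likelihood
#'
#' Sum over pairs of the bivariate-normal log density with common mean,
#' variance \eqn{a^2+d^2+c^2+e^2} and zygosity-specific covariance (see
#' module header). A non-positive-definite implied covariance returns
#' `-Inf`, never an error, so optimizers can reject it.
#'
#' @param pairs a [twin_pairs()] object.
#' @param model one of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param parameters named list/vector: `mu` plus the path coefficients the
#'   model uses (`a`, `d`, `c`, `e`); paths enter as squares.
#' @return scalar log-likelihood.
#' @export
twin_log_likelihood <- function(pairs, model, parameters) {
  model <- match.arg(model, TWIN_MODELS)
  if (identical(sort(names(parameters)), character(0)))
    tpk_stop("parameters must be named", "twinpk_invalid_input")
  p <- as.list(parameters)
  a <- p$a %||% 0; d <- p$d %||% 0; cc <- p$c %||% 0; e <- p$e %||% 0
  ic <- implied_cov(a^2, d^2, cc^2, e^2)
  st <- pair_suffstats(pairs)
  ll <- 0
  if (!is.null(st$MZ)) ll <- ll + biv_loglik(st$MZ, p$mu, ic$sigma2, ic$mz)
  if (!is.null(st$DZ)) ll <- ll + biv_loglik(st$DZ, p$mu, ic$sigma2, ic$dz)
  ll
}

# closed-form ML of the saturated model: per-zygosity exchangeable bivariate
# normal (mean_z, var_z, cov_z) = 6 parameters. Via sum/difference rotation
# u=(x1+x2)/sqrt2, v=(x1-x2)/sqrt2, independent with variances s2+c, s2-c.
fit_saturated <- function(pairs) {
  st <- pair_suffstats(pairs)
  ll <- 0; pars <- list()
  for (z in names(st)) {
    d <- pairs[pairs$zygosity == z, ]
    if (nrow(d) < 2) tpk_stop(
      sprintf("need >= 2 pairs per zygosity for the saturated model (%s)", z),
      "twinpk_insufficient_data")
    mu <- mean(c(d$x1, d$x2))
    vu <- mean(((d$x1 + d$x2) / sqrt(2) - sqrt(2) * mu)^2)
    vv <- mean(((d$x1 - d$x2) / sqrt(2))^2)
    s2 <- (vu + vv) / 2; cv <- (vu - vv) / 2
    if (s2 <= 0 || vu <= 0 || vv <= 0)
      tpk_stop("degenerate data: zero phenotypic variance",
               "twinpk_degenerate_data")
    pars[[z]] <- c(mean = mu, var = s2, cov = cv)
    ll <- ll + biv_loglik(st[[z]], mu, s2, cv)
  }
  list(log_likelihood = ll, n_parameters = 3L * length(st), parameters = pars)
}

# deterministic moment-based starts (Falconer-style) for each model
moment_starts <- function(pairs, model) {
  v <- stats::var(c(pairs$x1, pairs$x2))
  mu <- mean(c(pairs$x1, pairs$x2))
  covz <- function(z) {
    d <- pairs[pairs$zygosity == z, ]
    if (nrow(d) < 2) return(0)
    m <- mean(c(d$x1, d$x2))
    mean((d$x1 - m) * (d$x2 - m))
  }
  cmz <- covz("MZ"); cdz <- covz("DZ")
  clamp <- function(x) min(max(x, 0.02 * v), 0.96 * v)
  comp <- switch(model,
    ACE = c(a = clamp(2 * (cmz - cdz)), c = clamp(2 * cdz - cmz),
            e = clamp(v - cmz)),
    ADE = c(a = clamp(4 * cdz - cmz), d = clamp(2 * cmz - 4 * cdz),
            e = clamp(v - cmz)),
    AE  = c(a = clamp(cmz), e = clamp(v - cmz)),
    CE  = c(c = clamp((cmz + cdz) / 2), e = clamp(v - (cmz + cdz) / 2)),
    E   = c(e = v))
  base <- sqrt(comp)
  starts <- list(c(mu = mu, base))
  # deterministic perturbations around the moment start
  for (f in list(c(1.5, 0.7), c(0.7, 1.5), c(0.4, 1.2), c(1.2, 0.4))) {
    pert <- base * rep(f, length.out = length(base))
    starts[[length(starts) + 1L]] <- c(mu = mu, pert)
  }
  # equal-split start
  eq <- sqrt(rep(v / length(comp), length(comp)))
  names(eq) <- names(comp)
  starts[[length(starts) + 1L]] <- c(mu = mu, eq)
  starts
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Paths are parameterized as unconstrained reals entering the likelihood as
#' squares, so variance components are non-negative by construction and
#' boundary solutions (a component estimated at exactly 0) are attainable.
#' Optimization is multi-start (six deterministic starts derived from moment
#' estimates and fixed perturbations), Nelder-Mead followed by BFGS
#' polishing; the best converged solution is kept. `"saturated"` fits the
#' per-zygosity exchangeable bivariate normal (6 parameters) in closed form.
#'
#' @param pairs a [twin_pairs()] object.
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"` or `"saturated"`.
#'   `"ACDE"` is rejected: A, C and D cannot be jointly identified from
#'   twin pairs alone.
#' @return object of class `twin_model_fit`: standardized components
#'   `a2`, `d2`, `c2`, `e2` (proportions of the phenotypic variance),
#'   `raw_variance`, `mean`, `log_likelihood`, `n_parameters`, `aic`,
#'   `chi2_vs_saturated`, `df_vs_saturated`, `p_vs_saturated`.
#' @export
fit_twin_model <- function(pairs, model) {
  if (identical(model, "ACDE")) {
    tpk_stop(paste("ACDE is not identifiable in a twins-only design:",
                   "C and D cannot be jointly estimated"),
             "twinpk_unidentifiable_model")
  }
  model <- match.arg(model, c(TWIN_MODELS, "saturated"))
  if (stats::var(c(pairs$x1, pairs$x2)) <= 0) {
    tpk_stop("degenerate data: zero phenotypic variance",
             "twinpk_degenerate_data")
  }
  sat <- tryCatch(fit_saturated(pairs), twinpk_error = function(e) NULL)
  if (identical(model, "saturated")) {
    if (is.null(sat)) fit_saturated(pairs)  # re-raise the informative error
    fit <- list(model = "saturated", a2 = NA_real_, d2 = NA_real_,
                c2 = NA_real_, e2 = NA_real_, raw_variance = NA_real_,
                mean = NA_real_, log_likelihood = sat$log_likelihood,
                n_parameters = sat$n_parameters,
                aic = -2 * sat$log_likelihood + 2 * sat$n_parameters,
                chi2_vs_saturated = 0, df_vs_saturated = 0L,
                p_vs_saturated = NA_real_,
                saturated_parameters = sat$parameters,
                label = attr(pairs, "label"))
    class(fit) <- "twin_model_fit"
    return(fit)
  }

  paths <- model_paths[[model]]
  st <- pair_suffstats(pairs)
  negll <- function(theta) {
    p <- as.list(theta)
    names(p) <- c("mu", paths)
    a <- p$a %||% 0; d <- p$d %||% 0; cc <- p$c %||% 0; e <- p$e %||% 0
    ic <- implied_cov(a^2, d^2, cc^2, e^2)
    ll <- 0
    if (!is.null(st$MZ)) ll <- ll + biv_loglik(st$MZ, p$mu, ic$sigma2, ic$mz)
    if (!is.null(st$DZ)) ll <- ll + biv_loglik(st$DZ, p$mu, ic$sigma2, ic$dz)
    if (!is.finite(ll)) 1e10 else -ll
  }

  best <- NULL
  for (start in moment_starts(pairs, model)) {
    o <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    o <- tryCatch(
      stats::optim(o$par, negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) o)
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  if (is.null(best) || !is.finite(best$value)) {
    tpk_stop("twin model optimization failed to converge from all starts",
             "twinpk_convergence_failure")
  }
  theta <- as.list(best$par)
  names(theta) <- c("mu", paths)
  comp <- c(a2 = (theta$a %||% 0)^2, d2 = (theta$d %||% 0)^2,
            c2 = (theta$c %||% 0)^2, e2 = (theta$e %||% 0)^2)
  sigma2 <- sum(comp)
  ll <- -best$value
  k <- 1L + length(paths)
  chi2 <- if (is.null(sat)) NA_real_ else
    max(2 * (sat$log_likelihood - ll), 0)
  df <- if (is.null(sat)) NA_integer_ else sat$n_parameters - k
  fit <- list(model = model,
              a2 = comp[["a2"]] / sigma2, d2 = comp[["d2"]] / sigma2,
              c2 = comp[["c2"]] / sigma2, e2 = comp[["e2"]] / sigma2,
              raw_variance = sigma2, mean = theta$mu,
              log_likelihood = ll, n_parameters = k,
              aic = -2 * ll + 2 * k,
              chi2_vs_saturated = chi2, df_vs_saturated = df,
              p_vs_saturated = if (is.na(chi2)) NA_real_ else
                stats::pchisq(chi2, df, lower.tail = FALSE),
              label = attr(pairs, "label"))
  class(fit) <- "twin_model_fit"
  fit
}

#' @export
print.twin_model_fit <- function(x, ...) {
  cat(sprintf("Twin model %s%s\n", x$model,
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  if (!identical(x$model, "saturated")) {
    cat(sprintf("  a2 = %.3f  d2 = %.3f  c2 = %.3f  e2 = %.3f\n",
                x$a2, x$d2, x$c2, x$e2))
    cat(sprintf("  mean = %.4f  variance = %.4f\n", x$mean, x$raw_variance))
  }
  cat(sprintf("  lnL = %.3f  k = %d  AIC = %.2f\n",
              x$log_likelihood, x$n_parameters, x$aic))
  if (!identical(x$model, "saturated")) {
    cat(sprintf("  chi2 vs saturated = %.2f (df = %d, p = %.4g)\n",
                x$chi2_vs_saturated, x$df_vs_saturated, x$p_vs_saturated))
  }
  invisible(x)
}

#' Select the best-fitting twin model by AIC
#'
#' @param fits list of [fit_twin_model()] results on the same data.
#' @return the fit with the lowest AIC; ties go to the model with fewer
#'   parameters.
#' @export
select_model <- function(fits) {
  assert_that(length(fits) >= 1, "at least one fit required")
  aic <- vapply(fits, function(f) f$aic, 0)
  k <- vapply(fits, function(f) as.numeric(f$n_parameters), 0)
  fits[[order(aic, k)[1]]]
}

#' Bootstrap confidence intervals for standardized components
#'
#' Nonparametric pair-level bootstrap: pairs are resampled with replacement
#' within zygosity, the model is refitted, and percentile intervals of the
#' standardized components are reported. Replicates whose refit fails are
#' skipped and counted. A delta-method alternative (normal interval from the
#' numerically evaluated observed information, truncated to [0, 1]) is
#' available with `method = "delta"`.
#'
#' @param fit a converged [fit_twin_model()] result.
#' @param pairs the [twin_pairs()] the model was fitted to.
#' @param level confidence level; `level = 0` collapses to the point estimate.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for resampling.
#' @param method `"bootstrap"` (default) or `"delta"`.
#' @return list with per-component `ci` (matrix: component x low/high),
#'   `n_failed` replicates, and for the bootstrap the replicate draws.
#' @export
component_confidence_intervals <- function(fit, pairs, level = 0.95,
                                           n_boot = 1000L, seed = 1L,
                                           method = c("bootstrap", "delta")) {
  method <- match.arg(method)
  comps <- c("a2", "d2", "c2", "e2")
  est <- unlist(fit[comps])
  if (level <= 0) {
    ci <- cbind(low = est, high = est)
    rownames(ci) <- comps
    return(list(ci = ci, n_failed = 0L))
  }
  alpha <- (1 - level) / 2
  if (method == "delta") {
    se <- delta_component_se(fit, pairs)
    z <- stats::qnorm(1 - alpha)
    ci <- cbind(low = pmax(est - z * se, 0), high = pmin(est + z * se, 1))
    rownames(ci) <- comps
    return(list(ci = ci, n_failed = 0L))
  }
  idx <- split(seq_len(nrow(pairs)), pairs$zygosity)
  draws <- with_seed(stream_seed(seed, "bootstrap"), {
    reps <- matrix(NA_real_, n_boot, length(comps),
                   dimnames = list(NULL, comps))
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx, function(i) sample(i, length(i),
                                                    replace = TRUE)))
      bp <- pairs[take, ]
      class(bp) <- class(pairs)
      rf <- tryCatch(fit_twin_model(bp, fit$model),
                     twinpk_error = function(e) NULL)
      if (!is.null(rf)) reps[b, ] <- unlist(rf[comps])
    }
    reps
  })
  ok <- stats::complete.cases(draws)
  ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("low", "high")
  # a component estimated on the 0 boundary gets a one-sided interval
  ci[est < 1e-8, "low"] <- 0
  list(ci = ci, n_failed = sum(!ok), replicates = draws[ok, , drop = FALSE])
}

# finite-difference observed information -> delta-method SEs of the
# standardized components
delta_component_se <- function(fit, pairs) {
  paths <- model_paths[[fit$model]]
  sigma2 <- fit$raw_variance
  theta <- c(fit$mean, sqrt(unlist(fit[paste0(paths, "2")]) * sigma2))
  names(theta) <- c("mu", paths)
  f_ll <- function(th) {
    p <- as.list(th); names(p) <- c("mu", paths)
    twin_log_likelihood(pairs, fit$model, p)
  }
  H <- stats::optimHess(theta, f_ll)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA, length(theta),
                                                      length(theta)))
  comps <- c("a2", "d2", "c2", "e2")
  std <- function(th) {
    sq <- c(a = 0, d = 0, c = 0, e = 0)
    sq[paths] <- th[-1]^2
    tot <- sum(sq)
    c(a2 = sq[["a"]], d2 = sq[["d"]], c2 = sq[["c"]], e2 = sq[["e"]]) / tot
  }
  eps <- 1e-5 * pmax(abs(theta), 1)
  J <- matrix(0, length(comps), length(theta))
  for (j in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + eps[j]; tm[j] <- tm[j] - eps[j]
    J[, j] <- (std(tp) - std(tm)) / (2 * eps[j])
  }
  se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  names(se) <- comps
  se
}

#' Within-pair Pearson correlation with Fisher-z confidence interval
#'
#' Plain Pearson correlation of (sibling 1, sibling 2) as stored;
#' double-entry is not used. Order invariance comes from the canonical
#' within-pair ordering applied by [twin_pairs_from_table()].
#'
#' @param pairs a [twin_pairs()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param level confidence level.
#' @return list: `r`, `ci` (Fisher transform), `n_pairs`, `p`.
#' @export
pairwise_correlation <- function(pairs, zygosity, level = 0.95) {
  d <- pairs[pairs$zygosity == zygosity, ]
  if (nrow(d) < 3) {
    tpk_stop(sprintf("need >= 3 %s pairs for a correlation, have %d",
                     zygosity, nrow(d)), "twinpk_insufficient_data")
  }
  ct <- stats::cor.test(d$x1, d$x2, conf.level = level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       n_pairs = nrow(d), p = ct$p.value)
}
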