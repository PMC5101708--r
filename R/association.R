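# Genotype-phenotype and covariate-phenotype testing.

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a continuous outcome across ordered groups
#' (here: genotype by variant-allele dose). The statistic is
#' \eqn{JT = \sum_{i<j} U_{ij}} with \eqn{U_{ij}} the Mann-Whitney count of
#' pairs from the earlier group below the later group, ties counted half.
#' By default p-values use the tie-corrected normal approximation; with
#' `exact = TRUE` (total n at most `exact_limit`) the full permutation
#' distribution over distinct group assignments is enumerated.
#'
#' @param groups list of numeric vectors in increasing hypothesized order.
#' @param alternative `"increasing"`, `"decreasing"` or `"two.sided"`.
#' @param exact logical; exact enumeration (only for small samples).
#' @param exact_limit largest total n for which `exact = TRUE` is allowed.
#' @return list: `statistic`, `z`, `p`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                exact = FALSE, exact_limit = 12L) {
  alternative <- match.arg(alternative)
  assert_that(length(groups) >= 2, "need at least 2 ordered groups")
  assert_that(all(vapply(groups, length, 0L) > 0), "empty group")
  n <- vapply(groups, length, 0L)
  N <- sum(n)
  jt <- jt_statistic(groups)
  mu <- (N^2 - sum(n^2)) / 4
  if (exact) {
    assert_that(N <= exact_limit, sprintf(
      "exact enumeration limited to n <= %d (have %d)", exact_limit, N))
    dist <- jt_permutation_distribution(unlist(groups), n)
    p <- switch(alternative,
      increasing = mean(dist >= jt - 1e-9),
      decreasing = mean(dist <= jt + 1e-9),
      two.sided = mean(abs(dist - mu) >= abs(jt - mu) - 1e-9))
    return(list(statistic = jt, z = NA_real_, p = p, method = "exact"))
  }
  # tie-corrected variance (Hollander-Wolfe form)
  tie <- table(unlist(groups))
  t1 <- sum(tie * (tie - 1) * (2 * tie + 5))
  t2 <- sum(tie * (tie - 1) * (tie - 2))
  t3 <- sum(tie * (tie - 1))
  n1 <- sum(n * (n - 1) * (2 * n + 5))
  n2 <- sum(n * (n - 1) * (n - 2))
  n3 <- sum(n * (n - 1))
  v <- (N * (N - 1) * (2 * N + 5) - n1 - t1) / 72 +
    n2 * t2 / (36 * N * (N - 1) * (N - 2)) +
    n3 * t3 / (8 * N * (N - 1))
  if (v <= 0) {  # complete ties
    return(list(statistic = jt, z = 0, p = 1, method = "normal"))
  }
  z <- (jt - mu) / sqrt(v)
  p <- switch(alternative,
    increasing = stats::pnorm(z, lower.tail = FALSE),
    decreasing = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(statistic = jt, z = z, p = min(p, 1), method = "normal")
}

jt_statistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, "<")
    eq <- outer(xi, xj, "==")
    jt <- jt + sum(cmp) + 0.5 * sum(eq)
  }
  jt
}

# full permutation distribution of JT over distinct assignments of the pooled
# values to groups of the given sizes
jt_permutation_distribution <- function(pool, sizes) {
  res <- numeric(0)
  recurse <- function(remaining, gi, acc) {
    if (gi == length(sizes)) {
      acc[[gi]] <- remaining
      res[length(res) + 1L] <<- jt_statistic(acc)
      return(invisible())
    }
    cmb <- utils::combn(length(remaining), sizes[gi])
    for (col in seq_len(ncol(cmb))) {
      sel <- cmb[, col]
      acc[[gi]] <- remaining[sel]
      recurse(remaining[-sel], gi + 1L, acc)
    }
  }
  recurse(pool, 1L, vector("list", length(sizes)))
  res
}

#' Mann-Whitney U test
#'
#' Convention fixed as U = #(x < y) + 1/2 #(x = y) over all cross pairs
#' (x from `g1`, y from `g2`); large U means `g2` tends to exceed `g1`.
#' Exact p by enumeration of all group assignments when the combined n is at
#' most 12, otherwise tie-corrected normal approximation.
#'
#' @param g1,g2 numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` (g2 shifted above g1) or
#'   `"less"`.
#' @return list: `U`, `p`, `method`.
#' @export
mann_whitney <- function(g1, g2, alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  assert_that(length(g1) > 0 && length(g2) > 0, "empty group")
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  U <- sum(outer(g1, g2, "<")) + 0.5 * sum(outer(g1, g2, "=="))
  mu <- n1 * n2 / 2
  if (N <= 12) {
    pool <- c(g1, g2)
    cmb <- utils::combn(N, n1)
    dist <- apply(cmb, 2, function(sel) {
      a <- pool[sel]; b <- pool[-sel]
      sum(outer(a, b, "<")) + 0.5 * sum(outer(a, b, "=="))
    })
    p <- switch(alternative,
      greater = mean(dist >= U - 1e-9),
      less = mean(dist <= U + 1e-9),
      two.sided = mean(abs(dist - mu) >= abs(U - mu) - 1e-9))
    return(list(U = U, p = p, method = "exact"))
  }
  tie <- table(c(g1, g2))
  v <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  if (v <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu) / sqrt(v)
  p <- switch(alternative,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(U = U, p = min(p, 1), method = "normal")
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level.
#' @param n_tests number of tests.
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  assert_that(n_tests >= 1, "n_tests must be >= 1")
  alpha / n_tests
}

#' Multiple linear regression with per-factor marginal correlations
#'
#' Joint ordinary-least-squares fit of the phenotype on all factors. For
#' each factor the *marginal* Pearson correlation with the phenotype (and
#' its square) is reported next to the joint coefficient and p-value; the
#' overall R comes from the joint fit. Use `partial = TRUE` to report
#' partial correlations (from the joint fit t statistics) instead.
#'
#' @param phenotype numeric response.
#' @param factors data.frame of numeric predictors.
#' @param partial report partial instead of marginal correlations.
#' @return list: `per_factor` (factor, r, r2, coefficient, p),
#'   `overall` (R, R2, p), `fit` (the `lm` object).
#' @export
multiple_regression <- function(phenotype, factors, partial = FALSE) {
  assert_that(is.data.frame(factors) && ncol(factors) >= 1,
              "factors must be a data.frame with >= 1 column")
  n <- length(phenotype)
  assert_that(n > ncol(factors) + 1,
              "need more observations than factors + 1")
  const <- vapply(factors, function(x) stats::var(x) == 0, TRUE)
  assert_that(!any(const), paste("constant factor(s):",
                                 paste(names(factors)[const], collapse = ", ")))
  X <- cbind(`(Intercept)` = 1, as.matrix(factors))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    tpk_stop(paste("rank-deficient design; collinear factor(s):",
                   paste(bad, collapse = ", ")),
             "twinpk_rank_deficient")
  }
  dat <- data.frame(.y = phenotype, factors, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  coefs <- sm$coefficients[-1, , drop = FALSE]
  if (partial) {
    tv <- coefs[, "t value"]
    df_res <- fit$df.residual
    r <- tv / sqrt(tv^2 + df_res)
  } else {
    r <- vapply(factors, function(x) stats::cor(x, phenotype), 0)
  }
  per_factor <- data.frame(
    factor = names(factors), r = unname(r), r2 = unname(r^2),
    coefficient = unname(coefs[, "Estimate"]),
    p = unname(coefs[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE
  )
  fstat <- sm$fstatistic
  overall <- list(R = sqrt(sm$r.squared), R2 = sm$r.squared,
                  p = stats::pf(fstat[1], fstat[2], fstat[3],
                                lower.tail = FALSE))
  list(per_factor = per_factor, overall = overall, fit = fit)
}

#' Diet scores from questionnaire items
#'
#' Protein score = mean of meat, sausage, fish, dairy products and eggs;
#' vegetable score = mean of salad/raw vegetable and cooked vegetable.
#'
#' @param covariates data.frame with the seven diet item columns.
#' @return data.frame: `protein_score`, `vegetable_score` (one row per input
#'   row).
#' @export
diet_scores <- function(covariates) {
  protein_items <- c("meat", "sausage", "fish", "dairy_products", "eggs")
  veg_items <- c("salad_raw_vegetable", "cooked_vegetable")
  missing <- setdiff(c(protein_items, veg_items), names(covariates))
  if (length(missing)) {
    tpk_stop(paste("missing diet item(s):", paste(missing, collapse = ", ")),
             "twinpk_missing_column")
  }
  data.frame(
    protein_score = rowMeans(covariates[protein_items]),
    vegetable_score = rowMeans(covariates[veg_items])
  )
}

#' Verify declared zygosity from marker genotypes
#'
#' A pair is inferred MZ iff both siblings have identical genotypes at all
#' zygosity marker loci; any mismatch implies DZ; missing genotypes leave
#' the pair indeterminate (never guessed).
#'
#' @param genotype_table long table: `subject_id`, `locus`, `allele_count`.
#' @param pairs data.frame: `pair_id`, `subject_id`, declared `zygosity`.
#' @param loci character vector of zygosity marker names (default: the 23
#'   `ZYG` loci of [default_zygosity_loci()]).
#' @return data.frame per pair: `pair_id`, `declared`, `inferred`
#'   (`"MZ"`/`"DZ"`/`"indeterminate"`), `n_loci_compared`, `n_mismatch`,
#'   `concordant`.
#' @export
verify_zygosity <- function(genotype_table, pairs,
                            loci = default_zygosity_loci()$name) {
  gt <- genotype_table[genotype_table$locus %in% loci, ]
  out <- lapply(split(pairs, pairs$pair_id), function(p) {
    g <- lapply(p$subject_id, function(s) {
      gi <- gt[gt$subject_id == s, ]
      stats::setNames(gi$allele_count, gi$locus)[loci]
    })
    both <- !is.na(g[[1]]) & !is.na(g[[2]])
    if (length(p$subject_id) != 2L || !all(both)) {
      inferred <- "indeterminate"; nmis <- NA_integer_
    } else {
      nmis <- sum(g[[1]] != g[[2]])
      inferred <- if (nmis == 0L) "MZ" else "DZ"
    }
    data.frame(pair_id = p$pair_id[1], declared = p$zygosity[1],
               inferred = inferred, n_loci_compared = sum(both),
               n_mismatch = nmis,
               concordant = identical(inferred, p$zygosity[1]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genotype trend association for one locus
#'
#' Groups subjects by variant-allele count (0/1/2) and applies the
#' Jonckheere-Terpstra trend test to the phenotype. Non-biallelic genotype
#' codes (e.g. a rare third allele) must be excluded upstream unless an
#' ordering is supplied; allele counts outside 0/1/2 are rejected.
#'
#' @param phenotype numeric vector.
#' @param allele_count integer vector in 0/1/2 aligned to `phenotype`.
#' @param ... passed to [jonckheere_terpstra()].
#' @return list: `groups` (n, mean, sd per genotype present), `test`.
#' @export
genotype_trend_test <- function(phenotype, allele_count, ...) {
  assert_that(all(allele_count %in% 0:2),
              "allele counts must be 0, 1 or 2 (recode multi-allelic loci)")
  keep <- !is.na(phenotype) & !is.na(allele_count)
  phenotype <- phenotype[keep]; allele_count <- allele_count[keep]
  lv <- sort(unique(allele_count))
  groups <- lapply(lv, function(g) phenotype[allele_count == g])
  summ <- data.frame(
    allele_count = lv,
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 0)
  )
  test <- if (length(groups) >= 2) jonckheere_terpstra(groups, ...) else
    list(statistic = NA_real_, z = NA_real_, p = NA_real_,
         method = "not testable")
  list(groups = summ, test = test)
}
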