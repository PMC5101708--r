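# shared fixtures, built in code

# pair-wide table of per-subject phenotype (mean over occasions)
pair_wide <- function(phen, column = "log_cl") {
  agg <- stats::aggregate(phen[[column]],
                          by = phen[, c("subject_id", "pair_id", "sibling",
                                        "zygosity")], FUN = mean)
  agg <- agg[order(agg$pair_id, agg$sibling), ]
  s1 <- agg[agg$sibling == 1, ]
  s2 <- agg[agg$sibling == 2, ]
  data.frame(pair_id = s1$pair_id, zygosity = s1$zygosity,
             x1 = s1$x, x2 = s2$x, stringsAsFactors = FALSE)
}

within_pair_cor <- function(w, zyg) {
  d <- w[w$zygosity == zyg, ]
  stats::cor(d$x1, d$x2)
}

# strictly decreasing mono-exponential profile (positive at t = 0)
monoexp_profile <- function(c0 = 100, k = 0.1, times = c(0, 1:50),
                            dose = 50) {
  concentration_profile(times, c0 * exp(-k * times), dose_mg = dose)
}

# quick bivariate-normal twin pair draw
rpairs <- function(n_mz, n_dz, r_mz, r_dz, mu = 0, sd = 1) {
  gen <- function(n, r) {
    z0 <- stats::rnorm(n); z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    cbind(mu + sd * (sqrt(r) * z0 + sqrt(1 - r) * z1),
          mu + sd * (sqrt(r) * z0 + sqrt(1 - r) * z2))
  }
  m <- gen(n_mz, r_mz); d <- gen(n_dz, r_dz)
  twin_pairs(c(m[, 1], d[, 1]), c(m[, 2], d[, 2]),
             rep(c("MZ", "DZ"), c(n_mz, n_dz)))
}

# independent brute-force JT permutation oracle: enumerates every distinct
# assignment of the pooled values to the given group sizes and counts
# statistics at least as extreme as observed
jt_enum_oracle <- function(groups, alternative = "increasing") {
  jt_stat <- function(gl) {
    s <- 0
    for (i in seq_along(gl)[-length(gl)]) for (j in (i + 1):length(gl)) {
      for (x in gl[[i]]) s <- s + sum(x < gl[[j]]) + 0.5 * sum(x == gl[[j]])
    }
    s
  }
  pool <- unlist(groups)
  sizes <- lengths(groups)
  obs <- jt_stat(groups)
  mu <- (sum(sizes)^2 - sum(sizes^2)) / 4
  stats_all <- numeric(0)
  walk <- function(rem, gi, acc) {
    if (gi == length(sizes)) {
      acc[[gi]] <- rem
      stats_all[length(stats_all) + 1L] <<- jt_stat(acc)
      return(invisible())
    }
    cm <- utils::combn(length(rem), sizes[gi])
    for (cl in seq_len(ncol(cm))) {
      acc[[gi]] <- rem[cm[, cl]]
      walk(rem[-cm[, cl]], gi + 1L, acc)
    }
  }
  walk(pool, 1L, vector("list", length(sizes)))
  switch(alternative,
         increasing = mean(stats_all >= obs - 1e-9),
         decreasing = mean(stats_all <= obs + 1e-9),
         two.sided = mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9))
}
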