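#' Simulate twin log-clearance phenotypes
#'
#' Draws the variance components of log-clearance for every subject and
#' occasion. The additive-genetic component correlates 1 within MZ and 0.5
#' within DZ pairs, dominance 1 (MZ) and 0.25 (DZ), common environment 1 in
#' both, unique environment 0; occasion noise W is independent log-normal
#' with natural-scale CV `within_subject_cv`. Genotype and covariate effects
#' are *not* included here; [simulate_cohort()] adds them before building
#' concentration profiles.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per subject and occasion: `subject_id`,
#'   `pair_id`, `sibling` (1/2), `zygosity` ("MZ"/"DZ"), `occasion`,
#'   `log_cl` (log l/min) and `log_cl_subject` (the occasion-free subject
#'   level, i.e. without W).
#' @export
simulate_twin_phenotypes <- function(config) {
  validate_sim_config(config)
  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
  sigma2 <- log_scale_sigma2(config)
  sa <- sqrt(config$a2 * sigma2)
  sd_ <- sqrt(config$d2 * sigma2)
  sc <- sqrt(config$c2 * sigma2)
  se <- sqrt(config$e2 * sigma2)
  # arithmetic-mean parameterization: E[exp(components)] = exp(sigma2/2)
  mu <- log(config$mean_cl_l_per_min) - sigma2 / 2

  with_seed(stream_seed(config$seed, "phenotypes"), {
    mz <- zyg == "MZ"
    # additive genetic: shared + segregating parts (MZ share everything)
    a_sh <- stats::rnorm(n_pairs)
    a_u1 <- stats::rnorm(n_pairs); a_u2 <- stats::rnorm(n_pairs)
    A1 <- ifelse(mz, sa * a_sh, sa * (sqrt(0.5) * a_sh + sqrt(0.5) * a_u1))
    A2 <- ifelse(mz, sa * a_sh, sa * (sqrt(0.5) * a_sh + sqrt(0.5) * a_u2))
    # dominance: correlation 1 (MZ) / 0.25 (DZ)
    d_sh <- stats::rnorm(n_pairs)
    d_u1 <- stats::rnorm(n_pairs); d_u2 <- stats::rnorm(n_pairs)
    D1 <- ifelse(mz, sd_ * d_sh, sd_ * (0.5 * d_sh + sqrt(0.75) * d_u1))
    D2 <- ifelse(mz, sd_ * d_sh, sd_ * (0.5 * d_sh + sqrt(0.75) * d_u2))
    C <- sc * stats::rnorm(n_pairs)
    E1 <- se * stats::rnorm(n_pairs); E2 <- se * stats::rnorm(n_pairs)

    subj_level <- mu + c(rbind(A1 + D1 + C + E1, A2 + D2 + C + E2))
    n_subj <- 2L * n_pairs
    sdw <- sqrt(log(1 + config$within_subject_cv^2))
    # mean-preserving occasion noise: E[exp(W)] = 1
    W <- matrix(stats::rnorm(n_subj * config$n_occasions, sd = sdw) -
                  sdw^2 / 2, nrow = n_subj)

    out <- data.frame(
      subject_id = rep(sprintf("S%04d", seq_len(n_subj)),
                       each = config$n_occasions),
      pair_id = rep(sprintf("P%03d", rep(seq_len(n_pairs), each = 2L)),
                    each = config$n_occasions),
      sibling = rep(rep(1:2, n_pairs), each = config$n_occasions),
      zygosity = rep(rep(zyg, each = 2L), each = config$n_occasions),
      occasion = rep(seq_len(config$n_occasions), n_subj),
      log_cl_subject = rep(subj_level, each = config$n_occasions),
      stringsAsFactors = FALSE
    )
    out$log_cl <- out$log_cl_subject + c(t(W))
    out
  })
}

# --- genotypes ---------------------------------------------------------------

# haplotype frequencies chained along a block: adjacent loci get pairwise D'
block_haplotypes <- function(n_hap, freqs, dprime) {
  m <- length(freqs)
  hap <- matrix(0L, n_hap, m)
  hap[, 1] <- stats::rbinom(n_hap, 1L, freqs[1])
  if (m > 1) for (k in 2:m) {
    pa <- freqs[k - 1]; pb <- freqs[k]
    D <- dprime * min(pa * (1 - pb), (1 - pa) * pb)
    p_b_given_a1 <- (pa * pb + D) / pa
    p_b_given_a0 <- (pb - (pa * pb + D)) / (1 - pa)
    p <- ifelse(hap[, k - 1] == 1L, p_b_given_a1, p_b_given_a0)
    hap[, k] <- stats::rbinom(n_hap, 1L, p)
  }
  hap
}

#' Simulate genotypes and covariates for a twin cohort
#'
#' Genotypes descend from explicit simulated parental haplotypes: each pair
#' gets four founder haplotypes per block; DZ siblings draw independently one
#' maternal and one paternal haplotype, MZ siblings share a single draw, so
#' MZ genotypes are identical by construction and DZ sharing is exactly
#' Mendelian. Loci within a haplotype block are generated as chained
#' haplotypes with pairwise D' between adjacent loci. Covariates: sex and age
#' are shared within a pair (same-sex twins), BMI has shared plus unique
#' normal components, and the seven diet questionnaire items are integer
#' scores 1-6 with a pair-shared latent component.
#'
#' @param config a [sim_config()].
#' @param pair_structure data.frame with one row per subject: `subject_id`,
#'   `pair_id`, `sibling`, `zygosity` (as from [simulate_twin_phenotypes()],
#'   one row per subject-occasion is also accepted and deduplicated).
#' @return list with `genotype_table` (long: subject_id, locus, allele_count),
#'   `covariate_table` (one row per subject) and `log_cl_shift` (named numeric
#'   per subject: genotype + covariate contribution to log-clearance).
#' @export
simulate_genotypes_and_covariates <- function(config, pair_structure) {
  validate_sim_config(config)
  ps <- unique(pair_structure[, c("subject_id", "pair_id", "sibling", "zygosity")])
  ps <- ps[order(ps$pair_id, ps$sibling), ]
  pairs <- unique(ps[, c("pair_id", "zygosity")])
  n_pairs <- nrow(pairs)
  loci <- rbind(config$genotype_loci, config$zygosity_loci)
  loci$block <- ifelse(is.na(loci$block),
                       paste0(".solo_", loci$name), loci$block)

  geno <- with_seed(stream_seed(config$seed, "genotypes"), {
    counts <- matrix(0L, nrow = 2L * n_pairs, ncol = nrow(loci),
                     dimnames = list(ps$subject_id, loci$name))
    for (bl in unique(loci$block)) {
      idx <- which(loci$block == bl)
      # founders: 4 haplotypes per pair (2 maternal, 2 paternal)
      fh <- block_haplotypes(4L * n_pairs, loci$freq[idx], config$dprime)
      dim(fh) <- c(4L, n_pairs, length(idx))
      # transmission: which maternal (1/2) and paternal (3/4) haplotype
      pick_m1 <- stats::rbinom(n_pairs, 1L, 0.5) + 1L
      pick_p1 <- stats::rbinom(n_pairs, 1L, 0.5) + 3L
      pick_m2 <- stats::rbinom(n_pairs, 1L, 0.5) + 1L
      pick_p2 <- stats::rbinom(n_pairs, 1L, 0.5) + 3L
      mz <- pairs$zygosity == "MZ"
      pick_m2[mz] <- pick_m1[mz]; pick_p2[mz] <- pick_p1[mz]
      for (j in seq_along(idx)) {
        h <- fh[, , j]
        g1 <- h[cbind(pick_m1, seq_len(n_pairs))] +
          h[cbind(pick_p1, seq_len(n_pairs))]
        g2 <- h[cbind(pick_m2, seq_len(n_pairs))] +
          h[cbind(pick_p2, seq_len(n_pairs))]
        counts[, idx[j]] <- as.integer(c(rbind(g1, g2)))
      }
    }
    counts
  })

  cov_tab <- with_seed(stream_seed(config$seed, "covariates"), {
    sex_pair <- stats::rbinom(n_pairs, 1L, 0.5)          # 0 = F, 1 = M
    age_pair <- round(stats::runif(n_pairs, 18, 40))
    bmi_sh <- stats::rnorm(n_pairs, 0, 2)
    bmi <- 23 + rep(bmi_sh, each = 2L) + stats::rnorm(2L * n_pairs, 0, 1.5)
    diet_items <- c("meat", "sausage", "fish", "dairy_products", "eggs",
                    "salad_raw_vegetable", "cooked_vegetable")
    di <- sapply(diet_items, function(it) {
      lat <- rep(stats::rnorm(n_pairs, 0, 0.7), each = 2L) +
        stats::rnorm(2L * n_pairs, 0, 0.7)
      pmin(pmax(round(3.5 + lat), 1L), 6L)
    })
    cbind(
      data.frame(subject_id = ps$subject_id, pair_id = ps$pair_id,
                 zygosity = ps$zygosity,
                 sex = rep(sex_pair, each = 2L),
                 age = rep(age_pair, each = 2L),
                 bmi = round(bmi, 1), stringsAsFactors = FALSE),
      as.data.frame(di)
    )
  })

  eff <- config$covariate_effects
  # genotype contribution centered at its population expectation so locus
  # effects shift individuals, not the cohort mean
  shift <- drop(geno %*% loci$effect) - sum(2 * loci$freq * loci$effect) +
    (eff$sex %||% 0) * (cov_tab$sex - 0.5) +
    (eff$bmi %||% 0) * (cov_tab$bmi - 23) +
    (eff$protein_score %||% 0) *
      (diet_scores(cov_tab)$protein_score - 3.5) +
    (eff$vegetable_score %||% 0) *
      (diet_scores(cov_tab)$vegetable_score - 3.5)
  names(shift) <- ps$subject_id

  geno_long <- data.frame(
    subject_id = rep(rownames(geno), times = ncol(geno)),
    locus = rep(colnames(geno), each = nrow(geno)),
    allele_count = as.integer(geno),
    stringsAsFactors = FALSE
  )
  list(genotype_table = geno_long, covariate_table = cov_tab,
       log_cl_shift = shift)
}

# --- concentrations ----------------------------------------------------------

# one-compartment oral model, concentration in ug/l
one_compartment_conc <- function(t, dose_mg, cl_l_per_min, vz_l, ka_per_h) {
  ke <- 60 * cl_l_per_min / vz_l                    # 1/h
  if (abs(ka_per_h - ke) < 1e-9) ke <- ke * (1 + 1e-6)
  1000 * dose_mg * ka_per_h / (vz_l * (ka_per_h - ke)) *
    (exp(-ke * t) - exp(-ka_per_h * t))
}

#' Simulate concentration-time profiles
#'
#' Forward one-compartment first-order absorption model
#' \eqn{C(t) = \frac{D k_a}{V_z (k_a - k_e)} (e^{-k_e t} - e^{-k_a t})} with
#' \eqn{k_e = CL/V_z}, multiplied by log-normal assay noise. Concentrations
#' below the LLOQ are reported missing with a BLQ flag; the pre-dose sample
#' is 0.
#'
#' @param clearances data.frame with `subject_id`, `pair_id`, `zygosity`,
#'   `occasion` and `cl_l_per_min` (occasion-level clearance, natural scale).
#' @param config a [sim_config()].
#' @return concentration table: `subject_id`, `pair_id`, `zygosity`,
#'   `occasion`, `time_h`, `conc` (ug/l, `NA` when BLQ), `blq` (logical).
#' @export
simulate_concentration_profiles <- function(clearances, config) {
  validate_sim_config(config)
  assert_that(all(clearances$cl_l_per_min > 0), "clearances must be positive")
  tms <- config$sampling_times_h
  n_row <- nrow(clearances)
  with_seed(stream_seed(config$seed, "concentrations"), {
    sdlog <- sqrt(log(1 + config$assay_cv^2))
    conc <- matrix(0, n_row, length(tms))
    for (i in seq_len(n_row)) {
      conc[i, ] <- one_compartment_conc(tms, config$dose_mg,
                                        clearances$cl_l_per_min[i],
                                        config$vz_l, config$ka_per_h)
    }
    if (config$assay_cv > 0) {
      noise <- exp(matrix(stats::rnorm(n_row * length(tms), 0, sdlog),
                          n_row) - sdlog^2 / 2)
      conc <- conc * noise
    }
    conc[, tms == 0] <- 0
    out <- data.frame(
      subject_id = rep(clearances$subject_id, each = length(tms)),
      pair_id = rep(clearances$pair_id, each = length(tms)),
      zygosity = rep(clearances$zygosity, each = length(tms)),
      occasion = rep(clearances$occasion, each = length(tms)),
      time_h = rep(tms, n_row),
      conc = as.numeric(t(conc)),
      stringsAsFactors = FALSE
    )
    out$blq <- out$time_h > 0 & out$conc < config$lloq
    out$conc[out$blq] <- NA_real_
    out
  })
}

#' Simulate a complete twin cohort
#'
#' Runs [simulate_twin_phenotypes()], [simulate_genotypes_and_covariates()],
#' adds genotype and covariate effects to log-clearance, and builds the
#' concentration table via [simulate_concentration_profiles()]. Each stage
#' draws from its own seed stream derived from `config$seed`, so regenerating
#' one table never perturbs the others and identical seeds give
#' byte-identical cohorts.
#'
#' @param config a [sim_config()].
#' @return object of class `simulated_cohort`: list with
#'   `concentration_table`, `genotype_table`, `covariate_table` and `truth`
#'   (per-subject true clearance and generating components plus the config).
#' @export
simulate_cohort <- function(config) {
  phen <- simulate_twin_phenotypes(config)
  gc <- simulate_genotypes_and_covariates(config, phen)
  shift <- gc$log_cl_shift[phen$subject_id]
  phen$log_cl <- phen$log_cl + shift
  phen$log_cl_subject <- phen$log_cl_subject + shift
  occ <- data.frame(phen[, c("subject_id", "pair_id", "zygosity", "occasion")],
                    cl_l_per_min = exp(phen$log_cl), stringsAsFactors = FALSE)
  conc <- simulate_concentration_profiles(occ, config)
  subj <- unique(phen[, c("subject_id", "pair_id", "sibling", "zygosity",
                          "log_cl_subject")])
  truth <- list(
    config = unclass(config)[setdiff(names(config),
                                     c("genotype_loci", "zygosity_loci"))],
    subjects = data.frame(subj[, 1:4],
                          true_cl_l_per_min = exp(subj$log_cl_subject),
                          log_cl_subject = subj$log_cl_subject,
                          stringsAsFactors = FALSE),
    occasions = occ
  )
  structure(list(concentration_table = conc,
                 genotype_table = gc$genotype_table,
                 covariate_table = gc$covariate_table,
                 truth = truth),
            class = "simulated_cohort")
}

#' Write a simulated cohort to disk
#'
#' Writes `concentrations.csv`, `genotypes.csv`, `covariates.csv` and
#' `truth.json` under `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$concentration_table,
                   file.path(dir, "concentrations.csv"), row.names = FALSE)
  utils::write.csv(cohort$genotype_table,
                   file.path(dir, "genotypes.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariate_table,
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
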