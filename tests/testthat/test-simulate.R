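# synthetic twin-cohort generator

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(a2 = 0.5, c2 = 0.5, e2 = 0.2, d2 = 0),
               "equal 1")
  expect_error(sim_config(a2 = -0.1, c2 = 0.6, e2 = 0.5), ">= 0")
  expect_error(sim_config(n_occasions = 0), "n_occasions")
  expect_error(sim_config(sampling_times_h = c(0, 2, 1)), "increasing")
  expect_error(sim_config(sampling_times_h = c(1, 2, 3)), "start at 0")
  loci <- default_genotype_loci()
  loci$name[2] <- loci$name[1]
  expect_error(sim_config(genotype_loci = loci), "duplicated",
               class = "twinpk_duplicate_locus")
})

test_that("within-pair correlations match the implied values", {
  # pure common environment: both zygosities perfectly correlated
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, a2 = 0, d2 = 0,
                    c2 = 1, e2 = 0, within_subject_cv = 0, n_occasions = 1,
                    seed = 3)
  w <- pair_wide(simulate_twin_phenotypes(cfg))
  expect_gt(within_pair_cor(w, "MZ"), 0.99)
  expect_gt(within_pair_cor(w, "DZ"), 0.99)

  # ACE mixture: rMZ = a2 + c2, rDZ = a2/2 + c2
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, a2 = 0.5,
                    d2 = 0, c2 = 0.3, e2 = 0.2, within_subject_cv = 0,
                    n_occasions = 1, seed = 4)
  w <- pair_wide(simulate_twin_phenotypes(cfg))
  expect_lt(abs(within_pair_cor(w, "MZ") - 0.8), 0.02)
  expect_lt(abs(within_pair_cor(w, "DZ") - 0.55), 0.02)

  # pure unique environment: independence
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, a2 = 0, d2 = 0,
                    c2 = 0, e2 = 1, within_subject_cv = 0, n_occasions = 1,
                    seed = 5)
  w <- pair_wide(simulate_twin_phenotypes(cfg))
  expect_lt(abs(within_pair_cor(w, "MZ")), 0.03)
  expect_lt(abs(within_pair_cor(w, "DZ")), 0.03)
})

test_that("dominance component correlates 1 in MZ and 0.25 in DZ", {
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, a2 = 0, d2 = 0.8,
                    c2 = 0, e2 = 0.2, within_subject_cv = 0, n_occasions = 1,
                    seed = 6)
  w <- pair_wide(simulate_twin_phenotypes(cfg))
  expect_lt(abs(within_pair_cor(w, "MZ") - 0.8), 0.03)
  expect_lt(abs(within_pair_cor(w, "DZ") - 0.2), 0.04)  # ~4 sampling SEs
})

test_that("variance structure converges to its generating values", {
  cfg <- sim_config(n_mz_pairs = 10000, n_dz_pairs = 10000, a2 = 0.4,
                    d2 = 0, c2 = 0.3, e2 = 0.3, within_subject_cv = 0.25,
                    n_occasions = 3, seed = 8)
  ph <- simulate_twin_phenotypes(cfg)
  sigma2 <- log(1 + cfg$between_subject_cv^2)
  subj <- unique(ph[, c("subject_id", "log_cl_subject")])
  expect_equal(var(subj$log_cl_subject), sigma2, tolerance = 0.03)
  # occasion-level natural-scale CV around the subject mean
  cl <- exp(ph$log_cl)
  cv_hat <- sqrt(mean(tapply(cl, ph$subject_id, function(x) {
    (sd(x) / mean(x))^2
  })))
  expect_equal(cv_hat, 0.25, tolerance = 0.05)
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- sim_config(n_mz_pairs = 8, n_dz_pairs = 4, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_mz_pairs = 8, n_dz_pairs = 4, seed = 100)
  expect_false(identical(simulate_cohort(cfg)$concentration_table$conc,
                         simulate_cohort(cfg2)$concentration_table$conc))
})

test_that("pair bookkeeping invariants hold", {
  cfg <- sim_config(n_mz_pairs = 12, n_dz_pairs = 7, seed = 2)
  co <- simulate_cohort(cfg)
  subj <- unique(co$concentration_table[, c("subject_id", "pair_id",
                                            "zygosity")])
  per_pair <- table(subj$pair_id)
  expect_true(all(per_pair == 2))
  expect_true(all(tapply(subj$zygosity, subj$pair_id,
                         function(z) length(unique(z))) == 1))
})

test_that("MZ genotypes are identical, DZ sharing is Mendelian", {
  cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 60, seed = 21)
  co <- simulate_cohort(cfg)
  gt <- co$genotype_table
  subj <- unique(co$covariate_table[, c("subject_id", "pair_id", "zygosity")])
  wide <- reshape(gt, idvar = "subject_id", timevar = "locus",
                  direction = "wide")
  rownames(wide) <- wide$subject_id
  g <- as.matrix(wide[, -1])
  for (pid in unique(subj$pair_id)) {
    sibs <- subj$subject_id[subj$pair_id == pid]
    diff <- abs(g[sibs[1], ] - g[sibs[2], ])
    if (subj$zygosity[subj$pair_id == pid][1] == "MZ") {
      expect_true(all(diff == 0))
    } else {
      # siblings share at least one parental allele -> counts differ by <= 2
      expect_true(all(diff <= 2))
    }
  }
  # DZ pairs are not all identical (they would be with a broken generator)
  dz <- subj[subj$zygosity == "DZ", ]
  n_ident <- sum(vapply(unique(dz$pair_id), function(pid) {
    sibs <- dz$subject_id[dz$pair_id == pid]
    all(g[sibs[1], ] == g[sibs[2], ])
  }, TRUE))
  expect_lt(n_ident, length(unique(dz$pair_id)))
})

test_that("linkage equilibrium factorizes haplotype frequencies at D' = 0", {
  loci <- data.frame(name = c("L1", "L2"), freq = c(0.3, 0.6), effect = 0,
                     block = "B", stringsAsFactors = FALSE)
  cfg <- sim_config(n_mz_pairs = 1, n_dz_pairs = 25000, seed = 31,
                    genotype_loci = loci, dprime = 0, n_occasions = 1,
                    within_subject_cv = 0)
  ps <- simulate_twin_phenotypes(cfg)
  gc <- simulate_genotypes_and_covariates(cfg, ps)
  gt <- gc$genotype_table
  g1 <- gt$allele_count[gt$locus == "L1"]
  g2 <- gt$allele_count[gt$locus == "L2"]
  # allele-count correlation ~ 0 under linkage equilibrium
  expect_lt(abs(cor(g1, g2)), 0.02)
  expect_equal(mean(g1) / 2, 0.3, tolerance = 0.02)
  expect_equal(mean(g2) / 2, 0.6, tolerance = 0.02)
})

test_that("a genotype effect on log-clearance is recovered by regression", {
  loci <- data.frame(name = "L1", freq = 0.5, effect = 0.2, block = NA,
                     stringsAsFactors = FALSE)
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 5000, seed = 41,
                    genotype_loci = loci, within_subject_cv = 0,
                    n_occasions = 1, a2 = 0, c2 = 0, e2 = 1, d2 = 0)
  co <- simulate_cohort(cfg)
  gt <- co$genotype_table[co$genotype_table$locus == "L1", ]
  occ <- co$truth$occasions
  y <- log(occ$cl_l_per_min[match(gt$subject_id, occ$subject_id)])
  b <- coef(lm(y ~ gt$allele_count))[2]
  expect_equal(unname(b), 0.2, tolerance = 0.02 / 0.2)
})

test_that("concentration forward model matches the closed form and flags BLQ", {
  cfg <- sim_config(assay_cv = 0, seed = 1)
  cl <- data.frame(subject_id = "S1", pair_id = "P1", zygosity = "MZ",
                   occasion = 1, cl_l_per_min = 1)
  conc <- simulate_concentration_profiles(cl, cfg)
  ke <- 60 * 1 / cfg$vz_l
  ka <- cfg$ka_per_h
  t <- conc$time_h[-1]
  analytic <- 1000 * cfg$dose_mg * ka / (cfg$vz_l * (ka - ke)) *
    (exp(-ke * t) - exp(-ka * t))
  expect_equal(conc$conc[-1][!conc$blq[-1]],
               analytic[!conc$blq[-1]], tolerance = 1e-12)
  expect_identical(conc$conc[conc$time_h == 0], 0)
  # an absurd LLOQ flags every post-dose sample and NCA refuses the profile
  cfg_blq <- sim_config(assay_cv = 0, lloq = 1e6, seed = 1)
  conc2 <- simulate_concentration_profiles(cl, cfg_blq)
  expect_true(all(conc2$blq[conc2$time_h > 0]))
  prof <- concentration_profile(conc2$time_h, conc2$conc, conc2$blq, 50)
  expect_error(compute_pk_parameters(prof),
               class = "twinpk_insufficient_data")
})

test_that("cohort mean clearance matches the configured central value", {
  cfg <- sim_config(n_mz_pairs = 3000, n_dz_pairs = 1000, seed = 17,
                    n_occasions = 1)
  co <- simulate_cohort(cfg)
  expect_equal(mean(co$truth$subjects$true_cl_l_per_min), 0.97,
               tolerance = 0.03)
})

test_that("written cohorts round-trip through the readers", {
  cfg <- sim_config(n_mz_pairs = 4, n_dz_pairs = 2, seed = 5)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  conc <- read_concentration_table(file.path(dir, "concentrations.csv"))
  expect_equal(conc$conc, co$concentration_table$conc)
  gt <- read_genotype_table(file.path(dir, "genotypes.csv"))
  expect_equal(nrow(gt), nrow(co$genotype_table))
  cov <- read_covariate_table(file.path(dir, "covariates.csv"))
  expect_equal(cov$bmi, co$covariate_table$bmi)
})
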