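#' Default genotype locus panel
#'
#' Membrane-transporter variants typically assayed in probe-drug
#' pharmacogenetic studies (MDR1/ABCB1, MDR5/ABCB5, MRP2/ABCC2, BCRP/ABCG2),
#' with variant-allele frequencies close to European population values and an
#' additive effect (per variant allele, on log-clearance) carried by the MDR1
#' 1236T allele only: the other two MDR1 sites pick up association through
#' linkage disequilibrium within the shared haplotype block, which is the
#' pattern these variants show in vivo.
#'
#' @return data.frame with columns `name`, `freq` (variant allele frequency),
#'   `effect` (additive shift of log-clearance per variant allele) and `block`
#'   (haplotype-block id; `NA` = unlinked).
#' @export
default_genotype_loci <- function() {
  data.frame(
    name   = c("MDR1_C1236T", "MDR1_G2677T", "MDR1_C3435T",
               "MDR5_C392T", "MRP2_C24T", "MRP2_G1249A",
               "ABCG2_G34A", "ABCG2_C421A"),
    freq   = c(0.45, 0.44, 0.50, 0.055, 0.165, 0.17, 0.025, 0.125),
    effect = c(0.18, 0, 0, 0, 0, 0, 0, 0),
    block  = c("MDR1", "MDR1", "MDR1", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Default zygosity marker panel
#'
#' 23 unlinked polymorphic loci used only to verify zygosity: monozygosity is
#' concluded when both siblings are identical at all 23.
#'
#' @return data.frame in the [default_genotype_loci()] layout, zero effects.
#' @export
default_zygosity_loci <- function() {
  data.frame(
    name   = sprintf("ZYG%02d", 1:23),
    freq   = rep(c(0.2, 0.3, 0.4, 0.5), length.out = 23),
    effect = 0,
    block  = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a synthetic twin PK cohort
#'
#' Defines the generating model: log-clearance of subject j in pair i at
#' occasion k is
#' \deqn{\log CL_{ijk} = \mu + A_{ij} + D_{ij} + C_i + E_{ij} + g_{ij} + x_{ij} + W_{ijk}}
#' with additive-genetic (A), dominance (D), common-environment (C) and unique
#' environment (E) components whose variances are the stated proportions of
#' \eqn{\sigma^2 = \log(1 + \mathrm{CV}_b^2)}; g and x are genotype and
#' covariate contributions and W is log-normal occasion-to-occasion noise with
#' natural-scale coefficient of variation `within_subject_cv`. Concentration
#' profiles follow a one-compartment first-order absorption model with
#' apparent (bioavailability-normalized) clearance and volume.
#'
#' Defaults emulate a 50-mg three-occasion repeated-dose design: mean Cl/F
#' 0.97 l/min with ~43% between-subject CV, Vz 1115 l, sampling at
#' 0, 0.5, 1, 2, 3, 4, 5, 6, 22 h.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic pairs.
#' @param a2,d2,c2,e2 variance proportions of log-clearance; must sum to 1.
#' @param between_subject_cv natural-scale between-subject CV of clearance.
#' @param within_subject_cv natural-scale occasion-to-occasion CV.
#' @param n_occasions administrations per subject.
#' @param dose_mg administered dose (mg).
#' @param sampling_times_h strictly increasing sampling times, first element 0.
#' @param mean_cl_l_per_min median apparent clearance (l/min).
#' @param ka_per_h first-order absorption rate constant (1/h).
#' @param vz_l apparent volume of distribution (l).
#' @param assay_cv proportional (log-normal) assay noise CV.
#' @param lloq lower limit of quantification (ug/l); below it concentrations
#'   are reported missing with a BLQ flag.
#' @param seed integer RNG seed; all draws derive from it.
#' @param covariate_effects named list: additive effects on log-clearance of
#'   `sex` (coded 0/1, centered), `bmi` (per unit, centered at 23),
#'   `protein_score` and `vegetable_score` (per unit, centered at 3.5).
#' @param genotype_loci data.frame as [default_genotype_loci()].
#' @param zygosity_loci data.frame as [default_zygosity_loci()].
#' @param dprime pairwise D' between adjacent loci of a haplotype block.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 42L, n_dz_pairs = 13L,
                       a2 = 0, d2 = 0, c2 = 0.535, e2 = 0.465,
                       between_subject_cv = 0.43,
                       within_subject_cv = 0.25,
                       n_occasions = 3L,
                       dose_mg = 50,
                       sampling_times_h = c(0, 0.5, 1, 2, 3, 4, 5, 6, 22),
                       mean_cl_l_per_min = 0.97,
                       ka_per_h = 1.3,
                       vz_l = 1115,
                       assay_cv = 0.02,
                       lloq = 0.55,
                       seed = 1L,
                       covariate_effects = list(sex = 0, bmi = 0,
                                                protein_score = 0,
                                                vegetable_score = 0),
                       genotype_loci = default_genotype_loci(),
                       zygosity_loci = default_zygosity_loci(),
                       dprime = 0.9) {
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    a2 = a2, d2 = d2, c2 = c2, e2 = e2,
    between_subject_cv = between_subject_cv,
    within_subject_cv = within_subject_cv,
    n_occasions = as.integer(n_occasions),
    dose_mg = dose_mg, sampling_times_h = sampling_times_h,
    mean_cl_l_per_min = mean_cl_l_per_min, ka_per_h = ka_per_h, vz_l = vz_l,
    assay_cv = assay_cv, lloq = lloq, seed = as.integer(seed),
    covariate_effects = covariate_effects,
    genotype_loci = genotype_loci, zygosity_loci = zygosity_loci,
    dprime = dprime
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$a2, cfg$d2, cfg$c2, cfg$e2)
  assert_that(all(props >= 0), "variance proportions a2, d2, c2, e2 must be >= 0")
  assert_that(abs(sum(props) - 1) < 1e-12,
              "a2 + d2 + c2 + e2 must equal 1 (within 1e-12)")
  assert_that(cfg$n_mz_pairs >= 0 && cfg$n_dz_pairs >= 0 &&
                cfg$n_mz_pairs + cfg$n_dz_pairs >= 1,
              "at least one twin pair is required")
  assert_that(cfg$n_occasions >= 1L, "n_occasions must be >= 1")
  for (nm in c("between_subject_cv", "within_subject_cv", "assay_cv")) {
    assert_that(cfg[[nm]] >= 0 && cfg[[nm]] <= 1,
                sprintf("%s must lie in [0, 1]", nm))
  }
  assert_that(cfg$dose_mg > 0 && cfg$vz_l > 0 && cfg$ka_per_h > 0 &&
                cfg$mean_cl_l_per_min > 0,
              "dose, volume, absorption rate and clearance must be > 0")
  t <- cfg$sampling_times_h
  assert_that(length(t) >= 2 && t[1] == 0 && all(diff(t) > 0),
              "sampling_times_h must be strictly increasing and start at 0")
  loci <- rbind(cfg$genotype_loci, cfg$zygosity_loci)
  assert_that(!anyDuplicated(loci$name), "duplicated locus names",
              class = "twinpk_duplicate_locus")
  assert_that(all(loci$freq > 0 & loci$freq < 1),
              "allele frequencies must lie strictly in (0, 1)")
  assert_that(cfg$dprime >= 0 && cfg$dprime <= 1, "dprime must lie in [0, 1]")
  invisible(cfg)
}

# total between-subject variance of log-clearance
log_scale_sigma2 <- function(cfg) log(1 + cfg$between_subject_cv^2)
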