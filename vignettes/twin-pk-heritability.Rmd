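---
title: "Methods: twin-study heritability analysis of pharmacokinetic phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-study heritability analysis of pharmacokinetic phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpk)
```

## The problem

How much of the person-to-person variability in drug exposure is inherited?
For drugs that are eliminated essentially unchanged, exposure indexes the in
vivo activity of drug membrane transporters (MDR1/P-glycoprotein, MRP2,
BCRP, OATP1B1, OCT1), so the question becomes: is transporter activity
under genetic or environmental control? The classical design contrasts
monozygotic (MZ) twin pairs, who share all segregating genetic effects, with
dizygotic (DZ) pairs, who share on average half of the additive effects and
a quarter of the dominance effects. `twinpk` implements the full analysis
chain for a repeated-dose twin PK study of this kind — non-compartmental
exposure estimation, twin variance-component modeling, a repeated-measures
variance decomposition, and genotype/covariate association — together with a
synthetic cohort generator with known generating structure, so that every
stage is testable without access to subject-level clinical data.

## Non-compartmental analysis

Each subject-occasion profile is reduced to the standard battery:

* terminal slope: log-linear least squares of $\ln C$ on $t$ over trailing
  windows of the post-peak samples (the peak itself excluded). All windows
  of the last $k$ points, $k = 3, \dots$, are fitted and the window with the
  highest adjusted $R^2$ wins, ties going to the longer window. This mirrors
  the de-facto best-fit convention of commercial NCA software; the negated
  slope is $\lambda_z$, and $t_{1/2} = \ln 2/\lambda_z$.
* AUC by the linear-up/log-down trapezoidal rule: linear trapezoids on
  non-decreasing intervals, $\Delta t\,(C_1 - C_2)/\ln(C_1/C_2)$ on strictly
  decreasing positive intervals. The log rule is exact on exponential decay,
  so the whole chain is exact on mono-exponential profiles — a property the
  tests exploit.
* $AUC_\infty = AUC_{0\text{-}t_{last}} + \hat C(t_{last})/\lambda_z$, using
  the regression-predicted (not observed) concentration at the last
  quantifiable time; $AUC_{7h}$ uses log-linear interpolation at 7 h when no
  sample falls there (flag-free: on the falling limb interpolation is always
  log-linear, on the rising limb linear).
* $Cl/F = \mathrm{dose}/AUC_\infty$ and
  $V_z = \mathrm{dose}/(\lambda_z \cdot AUC_\infty)$; $C_{max}$ and
  $t_{max}$ are taken as observed, ties on the maximum resolved to the
  earliest time.

Units are fixed throughout: dose in mg, concentration in µg/l, time in h,
AUC reported in mg·min/l and clearance in l/min (so a constant 10 µg/l over
7 h is 4.2 mg·min/l).

Below-quantification (BLQ) samples are treated as 0 before the peak and
excluded after it; a profile whose remaining post-peak points number fewer
than three cannot support a terminal fit and is reported as a failure rather
than silently imputed. Per-subject parameters are arithmetic means over the
available occasions (up to three study days).

## Twin variance-component models

Pair phenotypes are modeled as bivariate normal with common mean $\mu$,
variance $\sigma^2 = a^2 + d^2 + c^2 + e^2$ and covariance

$$\mathrm{cov}_{MZ} = a^2 + d^2 + c^2, \qquad
  \mathrm{cov}_{DZ} = \tfrac12 a^2 + \tfrac14 d^2 + c^2,$$

the classical path coefficients for additive genetic (A), dominance (D),
common-environment (C) and unique-environment (E) components. C and D are
never co-estimated — they are not jointly identifiable from twins alone, and
`fit_twin_model` rejects `"ACDE"` with an explanatory error.

Numerical choices:

* paths enter the likelihood as squares of unconstrained reals, so variance
  components are non-negative by construction and boundary solutions
  (a component estimated at exactly 0) are ordinary interior points of the
  parameterization;
* the likelihood depends on the data only through per-zygosity sufficient
  statistics ($n$, $\sum x_1 + x_2$, $\sum x_1^2 + x_2^2$, $\sum x_1 x_2$),
  making each evaluation O(1) — this is what keeps large simulation-based
  checks cheap;
* optimization is multi-start: six deterministic starts (a Falconer-style
  moment estimate, four fixed perturbations of it, and an equal-split
  start), each run through Nelder-Mead and polished by BFGS, best solution
  kept;
* the saturated baseline is the per-zygosity exchangeable bivariate normal —
  zygosity-specific mean, variance and covariance, 6 parameters — fitted in
  closed form via the sum/difference rotation. Likelihood-ratio $\chi^2$ and
  degrees of freedom follow from that definition. Published tables from
  other software may use a richer saturated parameterization and hence
  report different $\chi^2$ values; the module reports its own LRT and makes
  no attempt to match any specific implementation's baseline.

Model choice is by AIC ($-2\ln L + 2k$), ties to the smaller model.
Confidence intervals for the standardized components default to a
pair-level nonparametric bootstrap (resampling pairs within zygosity,
percentile intervals, seeded); a delta-method interval from the observed
information is available by flag. Components on the 0 boundary get
one-sided intervals truncated at 0.

The analysis scale is the caller's choice: the pipeline fits clearance as
supplied (raw scale), while the simulation-based validation fits the
log-scale phenotype, where the generating decomposition is exactly
Gaussian. Both are legitimate; the standardized proportions differ slightly
between scales because the exponential transform is convex.

## The repeated-measures genetic component

With repeated administrations, occasion-to-occasion variability within a
subject bounds the "environmental noise floor". The genetic component is

$$rGC = (V_b - V_w)/V_b,$$

with $V_w$ the mean per-subject sample variance over occasions and $V_b$
the sample variance of per-subject occasion means — raw, with no subtraction
of $V_w/n_{occ}$ from $V_b$, following the cited formulation literally.
Because siblings are not independent units, the statistic is computed on 50
random one-sibling-per-pair subsets; the mean of the replicates is the
point estimate and their 2.5/97.5 percentiles form the 95% interval (the
replicate spread is the only stochastic element; the interval method is a
package choice). Negative values (when $V_w > V_b$) are reported as such and
flagged, never truncated — for parameters like $t_{max}$ with similar
within- and between-subject variance this is the expected outcome.

Under a generating model with subject-level variance $V_s$ and occasion
noise $V_o$, $E[V_w] = V_o$ and $E[V_b] \approx V_s + V_o/n_{occ}$, so the
population value of the statistic is
$(V_s - V_o(1 - 1/n_{occ}))/(V_s + V_o/n_{occ})$ — the round-trip tests
check convergence to exactly this expression.

## Association testing

* Jonckheere–Terpstra trend test across genotype groups ordered by
  variant-allele dose, statistic $\sum_{i<j} U_{ij}$ with half-credit for
  ties; p-values from the tie-corrected normal approximation (no continuity
  correction), or exact by full enumeration of distinct group assignments
  for total $n \le 12$. Multi-allelic genotypes (a rare third allele) are
  excluded from trend tests unless an ordering is supplied.
* Mann–Whitney U with the convention fixed as
  $U = \#(x < y) + \tfrac12\#(x = y)$ for group 1 vs group 2 (documented
  because conventions differ); exact for combined $n \le 12$, tie-corrected
  normal otherwise.
* Bonferroni: the working threshold is $\alpha/n_{tests}$ (0.05/10 = 0.005
  for a ten-polymorphism panel).
* Multiple regression by OLS; the per-factor `r` reported next to the joint
  coefficient is the *marginal* Pearson correlation of that factor with the
  phenotype (the dual reporting used in pharmacogenetic tables); partial
  correlations are available by flag. Sex is coded 0/1 (an arbitrary choice
  affecting the coefficient sign, not its correlation or p-value).
* Diet scores: protein = mean of meat, sausage, fish, dairy products, eggs;
  vegetable = mean of salad/raw vegetable and cooked vegetable.
* Zygosity verification: a pair is inferred MZ iff siblings are identical
  at all 23 marker loci; one mismatch implies DZ; missing genotypes leave
  the pair indeterminate rather than guessed.

## The synthetic cohort generator

The generator inverts the analysis assumptions so that every downstream
stage sees data with known truth:

* log-clearance of subject $j$ in pair $i$ at occasion $k$ is
  $\mu + A_{ij} + D_{ij} + C_i + E_{ij} + W_{ijk}$, components Gaussian on
  the log scale with variances $a^2, d^2, c^2, e^2$ proportions of
  $\sigma^2 = \log(1 + CV_b^2)$. Clearance is strictly positive and spans
  several fold between subjects, which makes the log scale the natural
  additive scale. A correlates 1 (MZ) / 0.5 (DZ), D 1 / 0.25, C 1 in both,
  E is independent.
* occasion noise $W$ is log-normal with natural-scale CV
  `within_subject_cv`; its distributional form is a package assumption (the
  design only fixes the CV). Both $W$ and the subject-level components are
  mean-corrected so that the natural-scale arithmetic mean equals
  `mean_cl_l_per_min`.
* defaults emulate a 50-mg, three-occasion repeated-dose design: mean Cl/F
  0.97 l/min with between-subject CV 0.43, $V_z$ 1115 l, $k_a$ 1.3 h⁻¹
  (placing $t_{max}$ near 2.6 h), sampling at 0, 0.5, 1, 2, 3, 4, 5, 6,
  22 h, LLOQ 0.55 µg/l (1.5 pmol/ml at talinolol's molar mass), assay CV
  2%, `within_subject_cv` 0.25 (reproducing a within-subject clearance
  variance near 0.06 (l/min)², i.e. up to threefold day-to-day variation in
  a 110-subject cohort), and a CE generating structure
  (c² = 0.535). A 2.5-mg single-occasion design is a parameter set
  (`dose_mg = 2.5`, sampling to 8 h), not a mechanistic saturation model —
  dose-dependent absorption is out of scope.
* concentrations follow a one-compartment first-order absorption model with
  apparent (bioavailability-normalized) clearance and volume, multiplied by
  log-normal assay noise; sub-LLOQ values are reported missing with a BLQ
  flag (never 0 or LLOQ/2 — the handling decision belongs to the NCA
  module); the pre-dose sample is 0.
* genotypes descend from explicit simulated parental haplotypes: four
  founder haplotypes per pair, DZ siblings drawing independently one
  maternal and one paternal haplotype, MZ siblings sharing a single draw.
  This makes MZ identity and DZ Mendelian sharing exact, rather than
  approximating DZ sharing with a 0.5 correlation. Loci within a haplotype
  block are chained with pairwise D′ (default 0.9) between adjacent loci —
  D′ between non-adjacent loci decays along the chain, which is a
  simplification, not a calibrated LD map. The default panel carries the
  locus effect on the MDR1 1236T allele only, with the other MDR1 sites
  picking up association through LD, the pattern such variants show in
  vivo. Genotype contributions are centered at their population expectation
  so locus effects shift individuals, not the cohort mean.
* covariates: sex and age are pair-shared (same-sex twins), BMI has shared
  and unique normal components, the seven diet items are integer 1–6 scores
  with a pair-shared latent part. Covariate effects on log-clearance apply
  to centered covariates and default to zero.
* randomness: each output table draws from its own sub-seed derived from
  the run seed (phenotypes, genotypes, covariates, concentrations), so
  adding loci never perturbs phenotype draws, and identical seeds give
  byte-identical cohorts.

What the generator deliberately does *not* emulate: dose-dependent
(saturable) transport, enterohepatic recirculation, sampling-time
deviations, assay batch effects, non-log-normal occasion noise, population
stratification, or genotyping error. Passing tests therefore demonstrate
the correctness of the estimators under the stated model, not robustness of
the original study design to these real-data features.

## Validation problem sizes

The test suite checks correlation identities and variance convergence at
10⁴ pairs per zygosity, CE/ACE recovery at 4–5×10³ pairs per zygosity
(where the ±0.02 Monte-Carlo band on standardized components is about two
standard errors), boundary behavior over 100 replicate fits, exact
enumeration oracles for the rank tests at n ≤ 12, and a full
simulate→NCA→rGC round trip at 100 MZ + 100 DZ pairs × 3 occasions — sizes
chosen to keep each property's Monte-Carlo error well inside its assertion
band.

## Known limitations

* Twin-only designs cannot separate C from D; with rDZ observed above rMZ,
  ACE-family fits push A to the boundary and the C/E split carries the
  signal.
* The bivariate-normal likelihood has no provision for covariate-adjusted
  means; adjust phenotypes (e.g. per-kg clearance, or residuals) before
  fitting.
* The rGC interval reflects only sibling-selection spread, not sampling
  variance of $V_w$ and $V_b$ themselves; it is narrower than a full
  bootstrap interval would be.
* Exact rank-test enumeration is combinatorial and capped at n ≤ 12;
  beyond that the tie-corrected normal approximation is used.
* NCA refuses profiles with fewer than three quantifiable post-peak
  points; with noisy flat absorption plateaus this can exclude occasional
  low-clearance profiles, mirroring the missing-data exclusions of real
  studies.
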