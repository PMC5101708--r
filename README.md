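# twinpk

Twin-study heritability analysis of pharmacokinetic phenotypes.

## The problem

For drugs eliminated essentially unchanged, between-subject variability in
exposure indexes the in vivo activity of drug membrane transporters (MDR1,
MRP2, BCRP, OATP1B1, OCT1). A repeated-dose twin design can split that
variability into additive genetic (A), dominance (D), common-environment
(C) and unique-environment (E) components by contrasting monozygotic (MZ)
and dizygotic (DZ) pairs. `twinpk` implements the complete analysis chain
for such a study, plus a synthetic cohort generator with known generating
structure so every stage is testable without subject-level clinical data:

1. **Non-compartmental analysis** — terminal slope λz by best-adjusted-R²
   log-linear regression, linear-up/log-down trapezoidal AUC,
   AUC∞ = AUC(0–t_last) + Ĉ(t_last)/λz, Cl/F = dose/AUC∞,
   Vz = dose/(λz·AUC∞), t½ = ln 2/λz, Cmax/tmax as observed.
2. **Twin variance-component models** — pairs are bivariate normal with
   variance a² + d² + c² + e² and covariance a² + d² + c² (MZ) or
   a²/2 + d²/4 + c² (DZ); ACE/ADE/AE/CE/E fitted by multi-start maximum
   likelihood with squared-path parameterization, compared by
   AIC = −2 lnL + 2k, likelihood-ratio tested against a 6-parameter
   saturated baseline, with pair-bootstrap confidence intervals.
3. **Repeated-measures genetic component** — rGC = (Vb − Vw)/Vb from the
   within- and between-subject variances of repeated administrations,
   averaged over 50 random one-sibling-per-pair subsets.
4. **Association testing** — Jonckheere–Terpstra trend test over
   variant-allele dose (exact by enumeration for small n), Mann–Whitney U,
   Bonferroni thresholding (0.05/10 = 0.005), multiple regression with
   marginal per-factor correlations, diet questionnaire scores, and
   genotype-based zygosity verification (MZ iff identical at all 23 marker
   loci).

See `vignettes/twin-pk-heritability.Rmd` for the models, assumptions and
design choices.

## Worked example

Simulate a 42 MZ + 13 DZ pair cohort (50 mg, three occasions, sampling
0–22 h) and run the full pipeline:

```r
library(twinpk)
cfg <- sim_config(seed = 2026)   # defaults: 42 MZ + 13 DZ, 50 mg x 3 occasions
report <- run_pipeline(cfg, n_boot = 200)
report
#> Twin PK heritability study report
#>   selected twin model: CE
#>   subjects analyzed: 110
#>   config hash: 66f296f07a323869dc59c7b67b14e365, seed 2026

subset(report$pk_summary, parameter == "cl_f")
#>   zygosity parameter  n      mean        sd    median       min      max ratio_max_min
#> 1       MZ      cl_f 84 0.9458692 0.4610917 0.8545415 0.3017966 2.775372      9.196167
#> 8       DZ      cl_f 26 0.9210949 0.3097479 0.9616650 0.3125018 1.406743      4.501554

report$model_comparison
#>       model           a2           d2        c2        e2     chi2          p      aic
#> 1       ACE 6.628935e-17 0.000000e+00 0.5158543 0.4841457 4.826304 0.08953262 115.9411
#> 2       ADE 5.093864e-01 3.196417e-11 0.0000000 0.4906136 5.730590 0.05696633 116.8453
#> 3        AE 5.093862e-01 0.000000e+00 0.0000000 0.4906138 5.730590 0.12547917 114.8453
#> 4        CE 0.000000e+00 0.000000e+00 0.5158537 0.4841463 4.826304 0.18496687 113.9411
#> 5 saturated           NA           NA        NA        NA 0.000000         NA 115.1148

subset(report$rgc, parameter %in% c("cl_f", "auc_inf"))
#>   parameter          vb          vw       rgc    ci_low   ci_high negative
#> 1      cl_f   0.1923887  0.06880515 0.6407411 0.5533090 0.7071338    FALSE
#> 2   auc_inf 887.2894523 401.39109042 0.5320528 0.2032013 0.7293276    FALSE
```

Reading the output: per-subject clearance (mean of up to three study days)
averages 0.95 l/min with a ~9-fold range in the MZ group. The CE model wins
on AIC: with this seed about 52% of the clearance variance is attributed to
common-environmental and 48% to unique-environmental effects (the
generating truth is c² = 0.535), while the ACE fit drives the additive
component to the 0 boundary — the signature of within-pair correlations
that do not decrease from MZ to DZ. The rGC table says ~64% of
between-subject clearance variance exceeds the occasion-to-occasion noise
floor.

A command-line wrapper over the same functions is installed at
`inst/scripts/twinherit.R`:

```sh
Rscript inst/scripts/twinherit.R simulate --out cohort/ --seed 5
Rscript inst/scripts/twinherit.R nca --conc cohort/concentrations.csv --dose-mg 50 --out pk.csv
Rscript inst/scripts/twinherit.R heritability --pheno pk.csv --column cl_f --out herit/
Rscript inst/scripts/twinherit.R rgc --pheno pk.csv --out rgc.csv --seed 2
```

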