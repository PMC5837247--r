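# statintol

Pharmacogenetic analysis of statin intolerance from electronic medical
records (EMR), for biostatisticians and pharmacoepidemiologists who
need the whole chain — phenotype, associate, pool — as tested,
reproducible code.

Statin intolerance has no laboratory gold standard, but it leaves
traces in prescribing data: switching between statins, discontinuation
at low doses, and on-therapy creatine kinase (CK) elevations.
`statintol` classifies statin users into:

* **GSI** (general statin intolerance) cases — on-statin CK above the
  sex-specific upper limit of normal plus ≥2 statin switches or total
  discontinuation — versus **ST1** tolerant controls (>90% coverage for
  ≥5 years at ≥40 mg/day simvastatin-equivalent, no switch, no
  discontinuation, normal CK);
* **LDI** (low-dose intolerance) cases — ≥2 distinct statins with at
  least one discontinued at its lowest approved starting dose,
  CK-independent — versus **ST2** controls (ST1 minus the CK
  criterion).

Association with a single biallelic variant (GRCh37 chr19:54759361
T>C) is tested under a dominant model contrasting T/T homozygotes with
C carriers: crude 2×2 odds ratios with Woolf standard errors
(`OR = ad/bc`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`), covariate-adjusted
logistic regression with backwards stepwise elimination (largest Wald
p first, genotype forced), genotype×treatment interaction and
genotype-stratified Cox models for randomized-trial data, and
inverse-variance fixed-effects meta-analysis:

    beta_pooled = sum(w_i * ln OR_i) / sum(w_i),  w_i = 1 / SE_i^2,
    SE_i = (ln U_i - ln L_i) / (2 * 1.959964)

A seeded synthetic cohort generator emulates the prescription, lab,
genotype and trial structure the analysis assumes, so the complete
pipeline runs and is tested without any patient data.

## Worked example

```r
library(statintol)

cfg    <- simulation_config(n_patients = 3000, seed = 11)
bundle <- simulate_observational_cohort(cfg)
bundle
#> Cohort bundle: 3000 patients, 127851 prescriptions, 9223 labs, records to 2013-07-31
#>   planted classes: GSI=151, GSI+LDI=9, indeterminate=655, LDI=153, ST=2032

assignments <- classify_cohort(bundle)
#> INFO: classified 3000 patients: GSI 160 case / 2032 control; LDI 162 case / 2032 control

tab <- build_analysis_table(assignments, bundle$genotypes, bundle$patients, "ldi")
#> INFO: LDI: 806 patient(s) unclassified, dropped
sel <- backward_eliminate(tab,
         full_terms = c("age", "female", "comedication", "t2d", "log10_ck"))
sel$fit
#> Logistic association model (n = 2194)
#> genotype_dom: OR 1.29 (95% CI 0.89-1.87), p = 0.18, n = 2194
#> age: OR 0.97 (95% CI 0.95-0.99), p = 0.0039, n = 2194
#> female: OR 4.47 (95% CI 2.95-6.78), p = 1.8e-12, n = 2194
#> log10_ck: OR 1020.22 (95% CI 371.99-2798.04), p = 2.7e-41, n = 2194
```

One seed of a 3000-patient cohort: the classifier recovers every
planted case (160 GSI = 151 + 9 dual-phenotype), stepwise elimination
drops the two noise covariates (`t2d`, then `comedication`), and the
genotype odds ratio 1.29 is one draw around the planted 1.43 — the test
suite shows the estimator is centred on the planted value over 200
replicates at n = 5000.

Pooling the four shipped per-study adjusted estimates:

```r
studies <- read_studies(statintol_example("figure1_studies.csv"))
pool_fixed_effects(studies)
#> Fixed-effects meta-analysis
#>   GoDARTS (LDI)          OR 1.43 (1.10-1.86)  weight 29.8%
#>   CPRD-STAGE (SIM)       OR 1.03 (0.72-1.49)  weight 15.6%
#>   PREDICTION-ADR (SIM)   OR 1.48 (1.05-2.10)  weight 17.1%
#>   JUPITER (myalgia)      OR 1.35 (1.07-1.71)  weight 37.5%
#>   Pooled OR 1.34 (95% CI 1.16-1.54), z = 3.97, p = 7.1e-05
#>   Heterogeneity Q = 2.57 (df = 3), p = 0.46
```

Asp247 homozygotes carry 1.34 (1.16–1.54) times the odds of an
intolerance-related outcome across the four studies.

An end-to-end run (`simulate` → `phenotype` → `associate` → `meta`)
with a manifest, atomic CSV/TSV/JSON outputs and optional VCF genotype
output is available as `run_pipeline("all", seed = 7, out_dir = "run")`
or from the shell via `inst/scripts/statintol.R`.

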