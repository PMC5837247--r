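---
title: "Phenotyping and pharmacogenetic analysis of statin intolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping and pharmacogenetic analysis of statin intolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statintol)
```

## The problem

Statin intolerance — the inability to stay on statin therapy, usually
because of muscle symptoms — has no laboratory gold standard. In
electronic medical records (EMR) it leaves characteristic traces:
repeated switching between statins, discontinuation at low doses, and
elevations of creatine kinase (CK) while on therapy. `statintol`
implements an EMR-based case/control machinery for this phenotype and
the downstream single-variant pharmacogenetic analysis: dominant-model
logistic association with covariate adjustment and backwards stepwise
elimination, genotype-by-treatment interaction and genotype-stratified
proportional hazards for randomized-trial data, and inverse-variance
fixed-effects meta-analysis across studies. The variant of interest is
a missense T>C polymorphism (chr19:54759361 on GRCh37, rs12975366); all
tests contrast Asp247 homozygotes (T/T, coded 1) with Gly carriers
(T/C or C/C, coded 0).

Because no patient-level data can ship with the package, a seeded
synthetic cohort generator produces observational cohorts and trial
datasets with the statistical structure the analysis assumes, so every
stage is exercised end to end by the test suite.

## Phenotype definitions

Two case definitions and two nested control definitions are
implemented, each a pure function of the prescription history, the CK
record and a `rules_config()`:

* **GSI (general statin intolerance) case**: any on-statin CK above the
  sex-specific upper limit of normal (ULN), together with two or more
  statin switches or total discontinuation of statin therapy.
* **ST1 control (statin tolerant)**: coverage above 90% of the therapy
  window (strict `>`), at least 5 years of therapy, a days-weighted
  mean dose of at least 40 mg/day simvastatin-equivalent, no counted
  switch, no total discontinuation, and consistently normal on-statin
  CK.
* **LDI (low-dose intolerance) case**: two or more distinct statins
  used, with at least one discontinued at (or below) its lowest
  approved starting dose — irrespective of CK, which makes this
  phenotype usable when CK itself is genetically confounded.
* **ST2 control**: all ST1 criteria except the CK criterion, so
  ST1 ⊆ ST2 by construction.

Candidate statin-induced myopathy is additionally flagged at on-statin
CK ≥ 4× ULN (inclusive).

Coverage is computed as the union of half-open covered intervals
`[start, start + days_supply)` clipped to the window — overlapping
scripts never double-count, and coverage is invariant under splitting a
script into abutting scripts. A switch is a drug change between
chronologically consecutive scripts; changes from simvastatin to
atorvastatin on or after the UK atorvastatin patent expiry (default
2012-05-01, configurable) are systematic formulary shifts and are not
counted. A drug is discontinued at a script when no same-drug script
starts within the permitted gap (default 90 days, strict `>`) after its
coverage ends; courses still covered, or within the gap, at the end of
records are treated as ongoing.

### Decisions where the rules are genuinely open

* The source definitions do not state ULN values; labs publish their
  own reference ranges. Defaults are 320 IU/L (male) and 200 IU/L
  (female) and live in `rules_config()` precisely so they can be
  replaced.
* The dose-equivalence ladder (atorvastatin 20 ≈ rosuvastatin 10 ≈
  simvastatin 40 ≈ pravastatin/fluvastatin/lovastatin 80 ≈
  pitavastatin 4 mg) and the lowest approved starting doses
  (simvastatin 10, atorvastatin 10, rosuvastatin 5, pravastatin 40,
  fluvastatin 20, lovastatin 20, pitavastatin 2 mg/day) are standard
  clinical tables and fully overridable.
* "Switched two or more times" is counted as switch *events* by
  default; counting *distinct statins* instead is available via
  `switch_metric = "distinct"`. Similarly the tolerant-control dose
  criterion uses the days-weighted *mean* equivalent dose by default,
  with `dose_metric = "minimum"` available.
* "Discontinued therapy" in the GSI rule means discontinuation of all
  statin therapy (a gap in the union of coverage); the LDI rule is
  per-drug, matching its per-statin wording.
* A patient can satisfy both the case and the control rule sets only in
  a contrived corner (an LDI-qualifying discontinuation combined with
  an uncounted post-patent switch); case status takes precedence, and
  a patient is never case and control of the same phenotype.
* Same-day scripts of different drugs are ordered by drug name; both
  contribute coverage and the transition counts once.

## Association models

`fit_logistic()` is a maximum-likelihood logistic fit with Wald
standard errors and two-sided p-values, the convention of the major
commercial packages this class of analysis is usually run in; 95%
intervals use z = 1.959964 and CK enters as log10(CK).
`backward_eliminate()` refits after removing the single non-forced term
with the largest joint Wald p-value above α (default 0.05, stated in
reports since the source analyses do not print theirs), so elimination
is deterministic; indicator blocks of a factor are removed as one block
on the block's joint Wald chi-square. The genotype term is always
forced. Separation and rank deficiency are reported as errors naming
the offending terms rather than silently returning huge coefficients.

Note one structural fact the GSI phenotype imposes: because GSI cases
are *defined* by elevated CK while ST1 controls are CK-normal, CK
separates cases from controls perfectly and cannot be a covariate for
GSI; the pipeline adjusts for CK only in the LDI model, which is the
reason the CK-independent LDI definition exists at all.

For trial data, `fit_interaction_model()` fits
`myalgia ~ genotype + arm + log10(final CK) + genotype×arm`
(logistic), and `fit_stratified_hazard()` fits a Cox proportional
hazards model of treatment within one genotype stratum, adjusted for
log10 final CK. Both paths are provided because published trial tables
of this design report odds ratios for the interaction model and hazard
ratios for the stratified analyses; the two agree closely at ~10%
cumulative incidence.

`contingency_or()` implements the crude 2×2 odds ratio with the Woolf
standard error `sqrt(1/a + 1/b + 1/c + 1/d)`; when a cell is zero the
Haldane–Anscombe 0.5 correction is applied to every cell and logged.
The exact Hardy–Weinberg test in `estimate_maf_and_hwe()` is the
conditional exact test on the heterozygote count given allele counts
(probability-ordered tail); it is cross-checked in the tests against a
Monte-Carlo allele-permutation oracle.

## Meta-analysis

`pool_fixed_effects()` pools per-study log odds ratios with
inverse-variance weights: `beta_i = ln(OR_i)` is reconstructed from the
printed point estimate, and the confidence interval supplies *only* the
standard error, `SE_i = (ln U_i − ln L_i) / (2 × 1.959964)` — the
standard practice for pooling published estimates. A warning fires when
a point estimate is more than 2% from the geometric mean of its bounds.
Cochran's Q is reported descriptively; no random-effects model is
offered because the target design specifies fixed effects. The package
ships the four-study table (`statintol_example("figure1_studies.csv")`)
of adjusted estimates — 1.43 (1.10–1.86), 1.03 (0.72–1.49),
1.48 (1.05–2.10), 1.35 (1.07–1.71) — whose pooled value the acceptance
script recomputes; the *adjusted* set is used because inverse-variance
recomputation with it uniquely reproduces the published pooled
estimate, an inference recorded here rather than a statement of the
source. Display comparisons round half away from zero to two decimals
(`round_half_up()`), matching how such tables are printed.

## What the synthetic generator emulates

`simulate_observational_cohort()` draws, per patient:

* a genotype under Hardy–Weinberg proportions at MAF 0.37 (0.40 in
  trial mode, matching the study populations being emulated);
* covariates with realistic margins but *independent* of each other —
  age ~ Normal(60, 10) truncated to [35, 90], sex 50/50, type-2
  diabetes 80%, interacting comedication 47%. The real covariate
  correlation structure of such cohorts is not published, so none is
  modelled, and that is a stated limitation rather than a guess;
* two latent intolerance liabilities (GSI, LDI), Bernoulli on the
  logistic scale with planted dominant odds ratios (defaults 1.96 and
  1.43) and modest covariate effects (female +0.28, age −0.20/decade,
  comedication +0.32 on the log-odds); the intercept is solved
  numerically so the marginal prevalence is 5%, the approximate
  prevalence of each phenotype among statin users in the cohorts being
  emulated. The liability is logistic, not probit, precisely so the
  planted odds ratio is the estimand of the downstream logistic fit;
* a prescription trajectory from an archetype consistent with the
  latent classes (switch sequences, total discontinuation,
  discontinuation at the lowest starting dose, control-qualifying
  84-days-supply/90-day-spacing courses anchored to the end of records,
  including a 30% sub-population of controls with the uncounted
  post-patent atorvastatin shift, and short unclassifiable histories
  for 25% of tolerant patients);
* CK labs: log-scale-free uniform draws at 30–85% of the sex-specific
  ULN for normals, multiplicative on-statin spikes for designated cases
  (mean fold-ULN 2.2; 15% of GSI cases reach the ≥4× ULN myopathy
  range), plus a pre-therapy CK and LDL for everyone. Only medians and
  extremes of real CK distributions are published, so the exact shape
  is a free choice.

Because the two liabilities are independent Bernoullis, excluding the
other phenotype's cases from a phenotype's control pool induces a small
genotype-dependent selection effect (of order 2–3% on the odds ratio);
the recovery suite's ±0.1 log-OR band absorbs it, and it is the price
of letting one cohort carry both phenotypes, as the emulated design
does.

`simulate_trial_cohort()` randomizes 1:1 independently of genotype and
draws exponential times to myalgia with rate
`0.0454 × 1.35^(T/T) × HR_stratum^(treated)` per person-year, censored
uniformly on 1.9 ± 0.4 years. The stratum treatment hazard ratios
default to 0.87 (T/T) and 1.23 (carriers) and the T/T multiplier to
1.35 — the published stratum estimates used as planted truths — and the
baseline rate 0.0454 was solved numerically (once, offline) so the
expected overall event fraction equals 837/8749 ≈ 9.6% under those
defaults. Final CK is log-normal with a weak genotype shift and no
dependence on the outcome, so adjusting for it downstream is harmless
by construction; trial censoring is administrative only, with no
competing risks.

What passing tests on these cohorts do **not** show: robustness to
correlated covariates, to misclassification noise in real prescription
records (the generator's trajectories are noise-free, which is why
classifier/truth agreement can be asserted at 100%), to informative
censoring, or to linkage structure around the variant (a single variant
is simulated, with no LD). Real-cohort descriptive statistics are
emulated only in their margins, never reproduced.

## Numerical choices and problem sizes

* Seeds: every generator call seeds the RNG from its configuration, so
  identical configuration and seed give byte-identical tables; the
  pipeline (`run_pipeline()`) threads one seed through all stages and
  writes a manifest with input/output lists and a config digest.
* Date arithmetic is integer days on half-open intervals; therapy years
  use 365.25-day years.
* The exact Hardy–Weinberg tail comparison uses a `1 + 1e-9` relative
  tolerance when summing probabilities no larger than the observed
  one, guarding against floating-point ties.
* Separation is declared when the logistic fit fails to converge or a
  non-intercept coefficient exceeds 15 on the log-odds scale.
* The recovery suites use 200 replicates at n = 5000 (observational,
  planted ORs 1.96/1.43), 200 replicates at n = 2000 (null, type-I
  error), and 200 replicates at n = 8749 (trial mode); these sizes give
  Monte-Carlo standard errors of the mean log effect below 0.01, an
  order of magnitude tighter than the ±0.1 recovery band.

## Known limitations

* The phenotyping rules assume complete prescribing records; gaps in
  real EMR capture would masquerade as discontinuations.
* Only one variant, one binary comedication flag, and no Read-code or
  free-text evidence are modelled.
* The fixed-effects pooling takes printed estimates at face value; no
  small-study or publication-bias diagnostics are included.
* The vectorized classifier (`classify_cohort()`) and the per-patient
  primitives (`classify_patient()`) are deliberately independent
  implementations of the same rules; their agreement is asserted by a
  property test rather than by sharing code.
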