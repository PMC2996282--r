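---
title: "Ranking insulin secretion indices by their power to detect genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking insulin secretion indices by their power to detect genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrank)
```

## The problem

Large genetic studies of beta-cell function need insulin secretion
phenotypes that are cheap to measure at scale. Fasting-state surrogates
(HOMA-B) and OGTT-derived indices (30-min insulin or C-peptide,
insulinogenic indices, corrected insulin response, oral disposition index,
a first-phase linear estimate, and ratios of analyte to glucose areas
under the curve) all claim to measure insulin release, but they are not
equally sensitive to genetically determined differences. `secrank`
implements a complete pipeline for deciding which index to use: compute
all twelve indices, associate each with each risk SNP under confounder
adjustment, convert each association's observed effect into a *least
significant number* (the sample size at which that effect would be
expected to reach significance), rank indices by lsn within each SNP, sum
the ranks over a SNP panel, and test each index's ranks against a
reference index with a Wilcoxon rank-sum test.

## Index definitions

All insulin and C-peptide concentrations are stored in pmol/l, glucose in
mmol/l, on the fixed OGTT grid {0, 30, 60, 90, 120} min. The scaled
trapezoid area is `0.5*(0.5*c0 + c30 + c60 + c90 + 0.5*c120)`; the 30-min
interval is never multiplied in because only AUC ratios are interpreted.
HOMA-B is `20*I0/(G0 - 3.5)` with insulin in uIU/ml; stored pmol/l values
are divided by 6.0 (the standard conversion; the constant is an argument
of `homa_b()` because assay calibrations differ). The 0-30 AUC ratios use
the two-point sum `(A0 + A30)/(G0 + G30)`, which equals the two-point
trapezoid ratio exactly because the weights cancel. The Matsuda
sensitivity index is computed directly in mmol/l and pmol/l with
unweighted five-point means; relative to the original mg/dl-uIU/ml
formulation this changes only a multiplicative constant, which the log
transform of the association stage absorbs into the intercept, so all
adjusted results are unit-invariant. The IVGTT acute insulin response uses
the half-weighted end-point sum over minutes 0-10; its weights sum to
2.5, so a constant profile `c` yields `2.5*c`.

A subject whose twelve secretion indices contain a negative value (a
falling 0-30 insulin increment, a 30-min glucose below the 3.89 mmol/l
CIR singularity, and so on) or an undefined one (singular denominator) is
excluded before any model fitting, and every exclusion is reported by id
and reason — in typical risk cohorts this affects on the order of 1% of
subjects. Glucose tolerance classes (NGT/IFG/IGT/diabetes, ADA fasting
and 2-h cutoffs) are provided for descriptive summaries only.

## Association model

For each (index, SNP) pair the package fits ordinary least squares on
log_e-transformed continuous variables: the log index on the untransformed
minor-allele count (0/1/2, additive coding) plus sex (binary indicator),
log age, log BMI and log Matsuda index. Rows with missing values, or
non-positive values destined for the log, are deleted listwise and
counted. Because age, BMI and insulin sensitivity are often skewed even
after transformation, a quartile-nominal mode replaces each of them by a
4-level factor cut at the sample quartiles (lower-inclusive; tied cuts
merge with a warning). A reverse direction — genotype as the numeric
dependent variable — is also provided; note that with identical rows the
forward and reverse p-values coincide exactly (both are the same partial
correlation), while the sums of squares, and therefore power and lsn,
differ between directions.

The fit reports the partial F of the tested term (t² for a 1-df term),
its hypothesis sum of squares `SSH = F * MSE`, and the residual mean
square, which are the inputs of the power stage. Validity against a
brute-force normal-equation solver is part of the test suite.

The adjusted correlation of each index with the IVGTT acute insulin
response is computed as `sign(beta)*sqrt(SSH/(SSH + SSE))` of the index
term in a model with AIR as dependent variable — a signed partial
correlation. Other definitions (standardised coefficient, correlation of
adjusted residuals) would give similar but not identical values; the
partial correlation was chosen because it derives from the same partial-F
machinery as the rest of the pipeline.

## Post-hoc power and least significant number

Both quantities take the observed effect at face value. With
noncentrality `lambda = SSH/MSE`, the post-hoc power at the observed n is
the probability that a noncentral F variable with (df1, n - k) degrees of
freedom exceeds the central critical value; `SSH = 0` gives power exactly
alpha. For the lsn, the squared effect size `delta² = SSH/n` and the
error variance `MSE` are held fixed, and the expected F at a candidate
size m is `(m * delta²/MSE)/df1` with the error degrees of freedom
recomputed as `m - k`; the lsn is the smallest integer m at which this
expected F meets the critical F at level alpha. The expected F is
increasing and the critical F decreasing in m, so the crossing is unique
and is found by doubling plus binary search; an exhaustive integer scan
serves as the test oracle. Recomputing df2 with m (rather than freezing it
at the observed fit) is a deliberate choice: it makes the lsn
self-consistent — the projected p-value at m = lsn is at most alpha and
at m = lsn - 1 is above it — which is the property the test suite
enforces. Alpha defaults to 0.05 throughout. Near-null associations have
astronomically large but finite lsn values; the pipeline keeps them
(they simply rank last) rather than failing.

Post-hoc power and lsn inherit the well-known circularity of
retrospective power analysis: they are monotone transforms of the
observed p-value, not independent evidence. Here they are used only as a
common currency for *comparing indices on the same cohort and SNP*, which
is exactly the setting where that monotonicity is a feature: within one
SNP column, a smaller lsn is equivalent to a stronger observed
association.

## Rank aggregation and the Wilcoxon comparison

Within each SNP column the twelve lsn values are converted to ascending
competition ranks (ties share the minimum rank; following ranks are
skipped — the convention is forced by published tables of this layout,
where two indices at the same rank sum are followed by a rank two
higher). Rank sums are accumulated over the full panel and over
mechanistic subsets (SNPs acting on glucose-stimulated secretion vs the
incretin axis), and the final ordering is again a competition ranking of
rank sums. Subset rank sums add up to the full-panel rank sum whenever
the subsets partition the panel.

Each index's per-SNP ranks are compared against a reference index
(HOMA-B by default) with a two-sample Wilcoxon rank-sum test.
`wilcoxon_exact()` enumerates all `choose(na+nb, na)` group assignments
of the pooled mid-ranks and doubles the smaller tail (capped at 1) —
exact even under ties. `wilcoxon_rank_sum(method = "normal")` gives the
tie-corrected normal approximation with continuity correction, the
convention of classical statistical packages. With six ranks per side the
two methods can disagree at the 0.05 boundary: on the shipped reference
matrix, the 30-min C-peptide column has an exact p of 42/924 = 0.0455 but
a normal-approximation p of 0.052. Analyses that aim to reproduce
legacy-software output should use the normal method; new analyses should
prefer the exact one. Subset-level Wilcoxon tests (3 ranks per side) are
computed on request but flagged exploratory — with n = 3 the smallest
achievable two-sided p is 0.1.

## The synthetic cohort generator

No subject-level data ship with the package; `simulate_cohort()` provides
cohorts whose statistical structure matches what the analysis assumes.
Four latent components per subject drive the curves:

* `S` — insulin sensitivity, lognormal, declining with BMI (elasticity
  -1.1) and age (-0.4%/year);
* `B` — basal secretion, compensating sensitivity (`S^-0.65`), scaled to
  a median fasting insulin of 47 pmol/l;
* `E` — early-phase amplitude (scale 400 pmol/l), expressed through a
  fast-decaying insulin kernel peaking at 30 min;
* `K` — incretin potentiation (scale 350 pmol/l), expressed through a
  late plateau kernel, and weighted about three times more strongly than
  `E` in the C-peptide curves, honouring C-peptide's longer half-life and
  the prolonged incretin exposure over the 30-120 min window.

Glucose rises from a lognormal fasting value (median 4.89 mmol/l, 8%
dispersion) by an excursion shrinking in `S*E`; minor alleles multiply
the routed component by a per-allele factor (0.9 by default, matching the
modest effects of confirmed risk variants); genotypes are Binomial(2,
maf) under Hardy-Weinberg equilibrium without linkage. All noise is
multiplicative lognormal, so the log-scale regression of the association
stage is correctly specified by default (`noise_model = "additive"`
provides a misspecification stress test). The default cohort size is
1350 with a 20% IVGTT subset, emulating a typical risk-cohort design.

The kernel weights were fixed by a design requirement, checked on a
10^4-subject diagnostic cohort: an early-phase allele must move the
early-window indices (IGI, CIR, 0-30 AUC ratios) with at least twice the
standardized effect it exerts on the late C-peptide ratio, and an
incretin allele the reverse. This dissociation is what makes the
end-to-end ranking property testable: on cohorts of 1500 with the effect
planted on one route, the matching index out-ranks HOMA-B in well over
80% of replicates.

What the generator does **not** emulate: family structure (the analysis
treats subjects as independent, so none is simulated), linkage
disequilibrium between SNPs, assay floor/ceiling effects, inter-visit
variability, and the enrichment of impaired-glucose-tolerance subjects
found in real risk cohorts. Passing tests on synthetic cohorts therefore
demonstrate the statistical machinery, not the biology of any particular
locus. Between-subject variance and assay noise are exposed as separate
knobs (`sd_latent`, `cv_*`) because published cohort tables conflate the
two.

## Numerical and design choices

* Exclusion handles the two failure modes distinctly: a finite negative
  secretion index sets the exclusion flag; a singular denominator yields
  an invalid (NA) index; both remove the subject, with the reason logged.
* Genotype degeneracy (a constant column) is a hard rank-deficiency error
  naming the collinear columns, not a silent drop.
* Quartile cuts are lower-inclusive at the 25/50/75 sample percentiles;
  a covariate constant after merging is dropped from the model with a
  warning rather than crashing the fit.
* `lsn()` errors beyond 1e9 when called directly (an effect that small is
  not meaningfully rankable in isolation); the pipeline raises the
  ceiling to 1e15 so null associations remain comparable.
* Competition ranking everywhere; mid-ranks only inside the Wilcoxon
  statistic, where they are standard.
* Problem sizes used by the test suite: 500 null cohorts of n = 1500 for
  type-I calibration, 100 cohorts per route for ranking recovery, 10^5
  Monte-Carlo draws for the noncentral-F oracle; these give comfortable
  margins on the tested bounds at a few minutes of runtime.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 1500, seed = 7,
                  snps = default_snp_panel(effect_early = 0.9,
                                           effect_incretin = 1))
run <- run_pipeline(config = cfg)
run$rank_table$final$ALL
```

With the effect planted on the early-phase route, the early-window
indices head the final ranking and HOMA-B drops to the bottom, while the
rank-only entry point `rank_only()` reproduces the published reference
aggregation (best index rank sum 24, HOMA-B 64) from the shipped lsn
matrix without any cohort at all.

## Limitations

The lsn layer compares indices *within* a cohort and SNP panel; absolute
lsn values depend on the observed effect sizes and should not be read as
prospective sample-size requirements. The Wilcoxon comparison treats the
six per-SNP ranks as independent observations, which they are not
(ranks within a SNP column are jointly constrained); the resulting p is a
descriptive summary, as in the original analysis design, not a calibrated
test. The association stage is plain OLS: cohorts with family structure
need a mixed-model extension before the power layer is trustworthy.
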