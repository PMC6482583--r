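---
title: "Threshold classifiers for metabolite-based disease stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold classifiers for metabolite-based disease stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabostrat)
library(dplyr)
```

## The problem

Circulating metabolites are attractive screening biomarkers: serum formate,
a one-carbon metabolite of the folate cycle, is depressed in breast and lung
cancer patients relative to healthy controls. A case-control study of one
disease against healthy controls, however, overstates how well such a
biomarker screens the general population, because other prevalent conditions
can move the same metabolite. Severe obesity is the salient confounder here:
a subset of obese individuals presents formate levels as low as those of
cancer patients, so a formate-only rule misclassifies them as cancer. At the
same time, obese patients — with or without type 2 diabetes — have elevated
circulating glucose, which a second biomarker can exploit.

`metabostrat` implements this multinomial stratification pipeline: a
binomial formate classifier, a two-biomarker (glucose, formate) decision
tree, threshold selection by relative mutual information, prevalence-
corrected error rates, and repeated Monte-Carlo cross-validation, together
with a synthetic-cohort generator so the whole analysis is runnable and
testable without access to patient measurements.

## Cohort model

A cohort is a tibble with one row per sample: `sample_id`, a `subtype` in
{H, BC, LC, ODminus, ODplus} (healthy, HER2+ breast cancer, non-small cell
lung cancer, severe obesity without/with type 2 diabetes), `formate` in mM,
`glucose` in mass-spectrometry peak-area units (deliberately not converted
to molar units, since decision thresholds for glucose are reported on the
peak-area scale), and optional further metabolite intensities. The merged
class used by the classifiers — healthy `h`, cancer `c` (BC and LC), obesity
`o` (ODminus and ODplus) — is always rederived from `subtype` by
`merge_class()`, never stored independently, so the two annotations cannot
drift apart. Formate and glucose are hard-required on every row; extra
metabolite channels may have missing values.

## The classifiers

The formate classifier imputes

* `c` if `formate < F_T`,
* `h` otherwise,

and the (glucose, formate) decision tree imputes

* `o` if `glucose > G_T`,
* `c` if `glucose < G_T` and `formate < F_T`,
* `h` otherwise.

All comparisons are strict; a sample exactly at a threshold falls into the
catch-all `h` branch. This matters in practice because candidate thresholds
are taken from the observed values themselves, so equality is common, and it
is stated prominently here because the case definitions could also have been
read with non-strict bounds. The tree topology is fixed (glucose first, then
formate); learning a topology is out of scope.

With the glucose threshold above every observed value the tree never imputes
`o` and coincides exactly with the formate classifier at the same `F_T` —
the binomial classifier is the degenerate case of the tree, and the test
suite asserts this identity.

## Threshold selection: relative mutual information

For reference classes `a` and imputed classes `b`, with joint fractions
`p_ab` and marginals `q_a`, `r_b`, the mutual information (in nats) is

    I(S*, S) = sum_ab p_ab ln( p_ab / (q_a r_b) ),

with the usual `0 ln 0 = 0` convention for empty cells, and the relative
mutual information normalises by the reference entropy:

    i(S*, S) = I(S*, S) / ( -sum_a q_a ln q_a ).

`i` is 1 exactly when the imputation reproduces the reference and 0 under
independence. It is preferred over accuracy-style objectives because it is
insensitive to which class is "positive" and extends unchanged from two to
three (or more) classes. The plug-in estimator is used deliberately — no
bias correction or shrinkage — because threshold selection only compares the
statistic across thresholds on the same sample set, where the plug-in bias
is common to all grid points.

`optimize_f()` scans the candidate formate thresholds on the healthy and
cancer samples of the training set; `optimize_gf()` scans the full Cartesian
glucose-by-formate grid on all three classes. Candidate grids are the sorted
distinct observed values plus one sentinel below the minimum and one above
the maximum, making the all-negative and all-positive rules reachable;
midpoints between observations are not added because with strict
inequalities they would change no classification. The search is exhaustive —
at cohort sizes of a few hundred the grid has at most a few tens of
thousands of cells, evaluated in a handful of vectorised matrix operations —
so no pruning heuristics are needed or wanted.

**Tie-breaking.** Several grid points frequently achieve the same objective
(any threshold between the same two data splits induces the same
partition). Among maximisers, the fit returns the smallest formate
threshold, then the smallest glucose threshold. The rule is value-based, so
the result is invariant to row order; ties are detected with a `1e-12`
tolerance because algebraically identical optima computed along different
grid paths can differ in the last floating-point ulp.

A permutation test (`permutation_pvalue()`) calibrates the achieved `i`:
reference labels are shuffled uniformly, and the add-one estimate
`p = (1 + #{i_perm >= i_obs}) / (1 + n_perm)` is reported, so p is never
exactly zero. Shuffling the reference or the imputed labels is equivalent
for this statistic (both preserve the marginals entering it); the reference
is shuffled here.

## Prevalence-corrected error rates

On a validation set `V`, the cancer true positive rate is
`TPR_C = |V∩C∩C*| / |V∩C|`. The false positive rate re-weights the obesity
group down to its population prevalence `p_O`:

    FPR_C = ( |V∩H∩C*| + x |V∩O∩C*| ) / ( |V∩H| + x |V∩O| ),
    x = p_O |V∩H| / |V∩O|.

The weight `x` makes the obesity samples count as if `p_O` obese individuals
accompanied every healthy control — the composition a screening population
would actually present — rather than the oversampled case-control ratio. At
`p_O = 0` the formula reduces exactly to the healthy-only rate.
`prevalence_fpr()` implements the direct multi-disease generalisation: each
non-target disease class `D_j` with prevalence `p_j` receives weight
`x_j = p_j |V∩H| / |V∩D_j|`, and numerator and denominator sum over all of
them; the two-class formula above is the single-confounder case. The weights
are recomputed from each validation set's own counts, never cached across
realisations.

A subtlety the test suite encodes: the corrected rate equals a physical
dilution experiment (each healthy control recruiting an obese sample with
probability `p_O`) as a *ratio of expected counts* — pooled false positives
over pooled set sizes — not as the expectation of per-resample ratios, which
differs by a Jensen gap at small `|V|`.

## Cross-validation

`cross_validate()` repeats: assign every sample to the training set with
probability 0.75 (Bernoulli per sample, following the resampling scheme
literally, so split sizes vary), fit thresholds on the training samples,
impute the validation samples, compute `TPR_C` and `FPR_C`. Each metric is
summarised by its median and 5th/95th percentiles over realisations. The
reference analysis used 100,000 realisations, which is the default;
estimates are stable well below that, and the package's own checks use
10,000 (directional comparisons) or a few hundred (exactness tests), sizes
chosen to keep the full suite quick on a laptop.

Realisations can be degenerate: the training set may lack a class needed for
fitting, or the validation set may lack cancer samples (TPR undefined),
healthy samples, or — when `p_O > 0` — obesity samples (FPR undefined).
Such realisations are skipped and tallied, never imputed with a made-up
value; dropping them is the only treatment that fabricates nothing, and the
skip counts are part of the result object. A single master seed draws one
sub-seed per realisation up front, so results are independent of evaluation
order.

ROC analyses set training = validation = full cohort and sweep the
threshold(s): `roc_curve_f()` yields the familiar curve; `roc_region_gf()`
evaluates every (G_T, F_T) pair, whose operating points fill a region of the
(FPR, TPR) plane rather than a curve — the geometric signature of a
two-biomarker rule.

## Differential statistics and quantification

`welch_volcano()` screens every metabolite channel between two subtypes:
fold change as the ratio of group means (arithmetic, on the raw scale; the
estimator is switchable to medians since the convention is not universal)
and a two-tailed unequal-variance Welch t-test via `stats::t.test()`.
Significance is flagged at the fixed tiers p < 1e-3 and p < 1e-6 — no
multiple-testing correction drives the flags, matching the fixed-tier
reporting convention, though a Benjamini-Hochberg column is emitted for
completeness. Metabolites with under two usable values per group, or zero
variance in both groups, are reported with an undefined p-value and flagged
rather than dropped. `correlation_perm()` pairs a Pearson correlation with a
two-sided permutation p (add-one rule, shuffling one vector, comparing
|r|).

`quantify_formate()` converts GC-MS peak areas to concentrations by ratio
against the d2-formate internal standard after blank subtraction:
`conc = standard_conc × (A_formate − A_blank,formate) / (A_d2 − A_blank,d2)`.
The effective in-sample standard concentration defaults to 25 µM (50 µM
spiked at 20 µL into a 40 µL sample) but is a parameter, since dilution
schemes vary. The assay underlying this formula is validated for 0–100 µM;
values outside that range are returned with a warning, not censored.

## The synthetic-cohort generator

No patient-level measurements are deposited for this study design, so
`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes; it is first-class, tested code, and the default
`default_cohort_spec()` *is* the study condition used throughout the tests
and the acceptance script:

* Group sizes 50/68/56/46/35 (H/BC/LC/ODminus/ODplus), the published study
  population. (The source reports slightly different sizes in two places —
  45 vs 46 obese non-diabetic, 58 vs 56 lung cancer; the tabulated values
  are used and sizes are parameters.)
* Lognormal marginals for both biomarkers: concentrations are positive and
  right-skewed, and box-plot summaries of such assays are routinely
  compatible with lognormality. No distributional family is published, so
  this is a modelling choice.
* Formate medians 0.080 mM (healthy) and 0.035 mM (cancer), bracketing the
  published optimal threshold 0.054 mM; obesity formate is a 50/50 mixture
  of the healthy-like and cancer-like components, realising the observation
  that obese formate spans healthy-like down to cancer-like values — the
  property that makes obesity a genuine confounder for the formate rule.
* Glucose medians 1.0e8 (H, BC, LC) versus 1.7e8/2.0e8 (ODminus/ODplus)
  peak-area units, bracketing the published glucose threshold 1.3e8;
  diabetic obesity is centred slightly higher, but both obesity groups are
  elevated.
* A sarcosine-like co-metabolite coupled to formate through a latent
  Gaussian on the log scale at correlation 0.6, emulating the reported
  formate–sarcosine correlation. The coupling standardises pooled
  log-formate empirically, so the channel inherits formate's group
  structure (depressed in cancer) automatically.

These parameter values were fixed once, from the ordering constraints and
the two published thresholds only; none of the per-group means or spreads is
a measured value. Consequently, passing tests demonstrate that the *method*
behaves as described on data with this structure — thresholds are recovered
between the group medians, prevalence correction moves the FPR in the
documented direction, the tree trades sensitivity for specificity — and not
that the published point estimates are reproduced. The generator also omits
known features of real data: batch structure, matrix effects, heavy tails
beyond lognormal, label noise in the reference annotation, and any
correlation between glucose and formate within groups.

## Numerical and degenerate-input choices

* Natural logarithms throughout the information quantities (nats).
* `0 ln 0 = 0` for empty joint cells; single-class reference labels make the
  normalisation undefined and raise an error rather than returning 0/0.
* Threshold equality → catch-all `h` branch (strict inequalities).
* Tie-break smallest `F_T` then smallest `G_T`, with a `1e-12` float
  tolerance.
* Undefined metrics return `NA_real_` (and are skipped/tallied by
  `cross_validate()`); genuinely invalid inputs (negative concentrations,
  unknown subtypes, duplicate ids) raise errors instead.
* Percentiles use the default type-7 quantile; with all-identical
  realisation values the 5/50/95 summary collapses to that value.
* CSV round-trips write numerics at 17 significant digits and parse them
  with correctly-rounded `as.numeric`, so written cohorts reload
  bit-identically.

## Worked example

```{r example}
cohort <- generate_cohort(seed = 1)
fit <- optimize_gf(cohort)
glance(fit)

cv <- cross_validate(cohort, classifier = "GF", p_o = 0.2,
                     n_realisations = 500, seed = 1)
tidy(cv)

welch_volcano(cohort, case = "BC", control = "H") |>
  arrange(p_value) |>
  head(3)
```

`autoplot(fit)` draws the relative-mutual-information heatmap over the
threshold grid, `plot_roc(roc_region_gf(cohort, p_o = 0.2))` the ROC region,
and `autoplot(cv)` the cross-validated performance summary.

## Limitations

* The decision tree is fixed at two biomarkers with a fixed split order;
  the framework generalises, the implementation deliberately does not.
* The plug-in mutual information is biased upward on small samples; this is
  immaterial for threshold *selection* but the achieved `i` should be
  calibrated with the permutation test, not read as an effect size.
* Prevalence correction assumes the case-control samples are exchangeable
  with the screening population within each class — it reweights
  composition, it cannot fix spectrum bias.
* Synthetic cohorts validate the machinery, not the clinical performance
  claims; only re-measured patient cohorts can do the latter.
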