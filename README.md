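# metabostrat

Multinomial biomarker stratification for serum/plasma metabolomics: threshold
classifiers selected by relative mutual information, with prevalence-corrected
error rates and Monte-Carlo cross-validation.

## The problem

Serum formate is depressed in breast and lung cancer patients, making it a
candidate screening biomarker. But a biomarker validated only against healthy
controls can fail in the population it is meant to screen: severe obesity also
depresses formate in a subset of patients, so a formate-only rule imputes many
obese individuals as cancer. Because obese patients have elevated circulating
glucose, a second biomarker restores specificity. `metabostrat` implements
this study design as a reusable pipeline for anyone evaluating metabolite
biomarkers against confounding diseases rather than healthy controls alone.

The core pieces:

* **Classifiers.** The binomial formate rule (`c` if `F_i < F_T`, else `h`)
  and the multinomial decision tree (`o` if `G_i > G_T`; `c` if `G_i < G_T`
  and `F_i < F_T`; `h` otherwise). All inequalities are strict; equality falls
  to the `h` branch.
* **Threshold selection.** Exhaustive search over observed-value grids
  maximising the relative mutual information
  `i(S*, S) = I(S*, S) / (−Σ_a q_a ln q_a)`, where
  `I = Σ_ab p_ab ln(p_ab / (q_a r_b))` compares imputed (`S*`) and reference
  (`S`) classifications; `i = 1` is a perfect match, `i = 0` independence.
  A seeded permutation test calibrates the achieved `i`.
* **Prevalence-corrected validation.** `TPR_C = |V∩C∩C*|/|V∩C|` and
  `FPR_C = (|V∩H∩C*| + x|V∩O∩C*|)/(|V∩H| + x|V∩O|)` with
  `x = p_O |V∩H|/|V∩O|`, which down-weights the oversampled obesity group to
  its population prevalence `p_O`. Repeated Bernoulli-0.75 train/validation
  splits give median (5–95%) performance summaries; ROC curves (one
  biomarker) and ROC regions (two biomarkers) cover the threshold space.
* **Differential statistics.** Welch-t volcano screens, Pearson correlation
  with permutation p, and internal-standard (d2-formate) peak-area
  quantification.
* **Synthetic cohorts.** A seeded lognormal generator reproducing the study's
  group structure (five groups H/BC/LC/OD−/OD+, sizes 50/68/56/46/35,
  cancer-depressed formate, obesity-elevated glucose, obesity formate
  spanning healthy-like to cancer-like, a correlated sarcosine-like channel),
  so the full analysis runs without access to patient data.

Everything is tibble-in / tibble-out with `tidy()`, `glance()`, `autoplot()`
methods, so results drop straight into dplyr/ggplot2 workflows.

## Worked example

```r
library(metabostrat)
library(dplyr)

cohort <- generate_cohort(seed = 1)   # default synthetic study population
fit <- optimize_gf(cohort)
fit
#> <threshold_fit> GF-classifier
#>   g_t: 132889559 (peak area)
#>   f_t: 0.0535514 mM
#>   relative mutual information: 0.6758
#>   trained on 255 samples ( h=50, c=124, o=81 )
```

The fitted thresholds sit between the synthetic group medians — glucose
1.33e8 peak-area units separating obesity from the rest, formate 0.054 mM
separating cancer from healthy — and the achieved relative mutual information
(0.68) says the three imputed classes recover most of the reference label
structure (1 would be a perfect match).

```r
cv <- cross_validate(cohort, classifier = "GF", p_o = 0.2,
                     n_realisations = 500, seed = 1)
cv
#> <cv_result> GF-classifier, p_o = 0.2, 500 realisations (train prob 0.75)
#>   TPR_C: 0.812 (0.687-0.931), 500 valid realisations
#>   FPR_C: 0.080 (0.000-0.310), 500 valid realisations
```

Across repeated 75/25 splits, with obesity weighted to a 20% population
prevalence, the tree detects a median 81% of cancer samples while imputing
8% of the prevalence-weighted non-cancer population as cancer.

```r
welch_volcano(cohort, case = "BC", control = "H") |> arrange(p_value)
#> # A tibble: 3 × 7
#>   metabolite fold_change  p_value tier     p_adj n_case n_control
#>   <chr>            <dbl>    <dbl> <chr>    <dbl>  <int>     <int>
#> 1 formate          0.468 1.18e-14 "**"  3.53e-14     68        50
#> 2 sarcosine        0.687 1.36e- 5 "*"   2.05e- 5     68        50
#> 3 glucose          0.988 6.37e- 1 ""    6.37e- 1     68        50
```

Formate shows the strongest depression in the synthetic breast-cancer group
(fold change 0.47 vs healthy, `**` = p < 1e-6); the sarcosine-like channel
tracks it at a weaker fold change, and glucose does not differ — exactly the
structure the generator encodes. `plot_volcano()`, `plot_roc()` and
`autoplot()` visualise each of these results, and `run_pipeline()` executes
the whole chain (simulate/read → fit → ROC → cross-validate → volcano) with
every artifact and a provenance report written to an output directory.

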