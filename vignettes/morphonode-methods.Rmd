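---
title: "Methods: the Morphonode ensemble for inguinal lymph-node ultrasound profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Morphonode ensemble for inguinal lymph-node ultrasound profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphonode)
```

## The problem and the unit of analysis

Preoperative staging of vulvar cancer hinges on whether the inguinal
lymph nodes are metastatic. Ultrasound is accurate in expert hands but
operator-dependent; the Morphonode model supports that assessment with a
multi-modular machine-learning predictor. The unit of analysis is the
*groin*: each patient contributes one or two inguinal regions, and a
groin is labelled metastatic when at least one of its nodes is positive
at histology.

Each groin is described by 14 modelling features (`us_features()`):

* two continuous size measurements in mm — **short axis** and **cortical
  thickness** — the strongest single discriminators;
* three binary **metastatic markers** — absence of the nodal core sign,
  perinodal hyperechogenic ring, cortical interruption — rare but almost
  pathognomonic (positive predictive value at or above 0.85);
* nine ordinal/categorical morphology and vascular features
  (echogenicity, focal intranodal deposits, vascular flow localization,
  cortical thickening, vascular flow architecture, cortical–medullar
  interface distortion, shape, grouping, color score).

Two further measurements (medulla, long axis) are recorded in the CSV
schema but excluded from modelling as uninformative.

### Dichotomization

The categorical features enter the risk models through a fixed *range of
positivity* per feature (e.g. vascular architecture 2–4 =
scattered/branched/chaotic; shape 3 = irregular; color score 3–4). The
code books below each printed positivity range are defined as the
smallest consistent extension of those ranges. Two points were genuinely
open and are resolved here as package policy:

* the interface-distortion scale prints positivity "2–3" but also defines
  a code 4 ("medulla not visible"); we treat 4 as positive, reading the
  scale as monotone in severity;
* the two continuous features are **not** dichotomized anywhere: the
  positivity ranges are stated only for categorical predictors, and
  binarizing mm-scale measurements would discard the model's strongest
  signal. `dichotomize()` is the single place this policy lives, so it
  can be revisited without touching the models.

## The synthetic cohort generator

The study's 237-groin dataset is not publicly deposited, so
`generate_cohort()` produces cohorts with the statistical structure the
model assumes; every downstream module is trained and verified on them.
The defaults *are* the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_groins` | 237 | study size |
| `prevalence` | 75/237 | 75 metastatic vs 162 non-metastatic groins |
| `marker_rates` | (0.45, 0.02) | closed-form marker PPV 0.45π/(0.45π+0.02(1−π)) = 0.912 at π = 75/237, inside the ≥ 0.85 marker band |
| `continuous_effect` | 1.14 | log-scale standardized shift; normal-theory AUC Φ(1.14/√2) = 0.790, matching the printed 79.1–79.3% |
| `multinode_prob` | (0.45, 0.15) | multi-node disease more frequent in marker-positive groins (mirrors the printed MET–HMR multi-node excess of ~31%) |
| `bilateral_fraction` | 110/127 | 127 patients contributing 237 groins |
| `patient_effect_sd` | 0.5 | within-patient outcome correlation, a free parameter |

Outcomes are drawn through a Gaussian copula: bilateral groins share a
patient-level latent normal, and each groin's outcome thresholds its
latent value at the prevalence quantile. This keeps the *marginal*
prevalence exact (a logit random-intercept construction would inflate it
by several groins per cohort) while still inducing within-patient
correlation. The two size features are bivariate log-normal on the log
scale (positive support and right skew, as size measures typically are;
within-class log-correlation 0.4), with the metastatic class shifted by
`continuous_effect` standard deviations. Ordinal features are class-
tilted multinomials; the tilts are calibrated so each feature's
single-feature AUC falls in the band its printed priority class implies
(roughly 0.63–0.73), and every dichotomized non-marker PPV stays well
below the 0.85 marker threshold.

What the generator does *not* emulate: the real inter-feature
correlation structure (unpublished), the subjective LN1–LN5 assessment,
and any image-level information. Passing tests on synthetic cohorts
therefore demonstrate that the *machinery* is correct and recoverable —
not that a synthetically trained model is clinically valid.

One consequence worth stating: with the calibrated marker rates, the
three binary markers are conditionally clean Bernoulli signals and tend
to occupy the top of the random-forest importance ranking on synthetic
cohorts, whereas the study reports the two size features as the top
stable ranks. The size features still dominate the ordinal block and sit
in the upper half of the ranking; the inversion is a property of the
synthetic marker model, not of the ranking code.

## Module 1 — random-forest majority vote

`split_subsets()` partitions the cohort into 5 random subsets,
stratified by outcome, sizes differing by at most one (237 → 48, 48, 47,
47, 47). `train_ensemble()` then trains one forest member per left-out
subset on the remaining four (nested cross-validation: the inner 4-fold
loop over those subsets tunes the features-per-split parameter, grid
2/3/5/7; 500 trees by default; all randomness derived from one master
seed). Each member's held-out confusion matrix is retained.
`predict_vote()` applies the 3-of-5 majority; the vote is symmetric in
the members and monotone in each vote.

Feature ranking averages the permutation importance (mean decrease in
accuracy) and the impurity importance (mean decrease in Gini) over
members, min-max normalizes each index across the 14 features, and
averages the two; ties break lexicographically.

The reading "each member trained on exactly four subsets, validated on
the fifth" is the only one that yields exactly five classifiers each
with an independent validation subset, and is adopted. Class weights are
off by default (a `classwt` switch exists).

## Module 2 — binomial risk model and thresholds

`fit_rbm()` fits a binomial GLM (logit link) of the outcome on the
dichotomized categorical block plus the raw continuous features. The
"robust" aspect is implemented as a *bias-reduction fallback*: when the
ML fit shows complete or quasi-complete separation (extreme fitted
probabilities, non-convergence, or runaway coefficients), the model is
refitted with Firth's adjusted-score estimator (implemented by
penalized IWLS) and flagged. Percentile 95% intervals per coefficient
come from a nonparametric bootstrap over groins (2000 resamples by
default).

`select_thresholds()` scans candidate cut-offs — midpoints of the sorted
unique risks, plus the smallest risk so that predict-all-positive is
attainable — for two optima on the rule "positive when risk ≥ t":

* **t_F1**: maximizes the F1 score (ties → lower t);
* **t_SeSp**: maximizes min(sensitivity, specificity), ties broken by
  larger Se + Sp, then lower t. "Maximizing both sensitivity and
  specificity" is ambiguous; the max–min reading is the default and a
  Youden option (`sesp_rule = "youden"`) is provided.

The published pair (0.23, 0.29) ships as frozen constants
(`rbm_published_thresholds()`) for inference; retraining recomputes both
from data. `stratify_risk()` maps a risk to low (< t_F1), moderate
(t_F1 ≤ r ≤ t_SeSp, both boundaries inclusive) or high (> t_SeSp).

## Module 3 — marker screen and risk-signature tree

`compute_feature_ppv()` estimates each dichotomized feature's positive
predictive value; features at or above 0.85 become metastatic markers
(`extract_markers()`; the threshold is inclusive). Any positive marker
leads directly to the **MET** signature: point risk ~1.00 with two or
more markers, 0.88 (the 0.86–0.90 interval midpoint) with exactly one.

Marker-negative profiles go through a Gini decision tree
(`build_tree()`): recursive binary partitioning, pruned to at most three
leaves, labelled **HMR / MMR / LMR** by descending leaf risk. The tree
is grown with rpart's anova method on the 0/1 outcome: for a binary
outcome the within-node sum of squares n·p(1−p) is exactly the weighted
Gini impurity (up to a constant factor), and the anova complexity
sequence tracks impurity reduction, so pruning selects the
lowest-impurity 3-leaf subtree even at the low prevalence of the
marker-negative subset — where classification-mode pruning would retain
no splits at all, because no split changes the majority class. Leaf
risks are leaf metastatic fractions with percentile bootstrap intervals
(resampling groins through the fixed tree).

An MMR profile with **at least two** of the nine positive diagnostic
covariates escalates to the higher MMR point risk. The published point
risks (MET ≈ 1.00 / 0.88, HMR 0.81, MMR 0.16, MMR-escalated 0.55, LMR
0.04, with their intervals) ship as frozen constants for inference
(`signature_published_risks()`); `risk_source = "trained"` re-estimates
them. The internal split structure of the original tree is not printed
anywhere, so it is learned from data by the stated procedure — which is
also why a synthetically trained tree makes no clinical claim.

## Module 4 — prediction error and similarity profiling

The reliability of a prediction is scored as *E = b0[signature] + b·L*,
where *L = −(y ln p + (1−y) ln(1−p))* is the logistic loss between the
forest label y and the binomial risk p (p clipped at 1e−15): the more
the two modules disagree, the larger L. `calibrate_error_model()`
estimates b0[s] as the mean per-groin Brier score (p − outcome)² within
signature group s (empty groups fall back to the global mean, flagged),
and b as the through-the-origin least-squares slope of the residual
Brier score on L. A negative slope would reward disagreement, so b is
clamped at zero and flagged. Predictions with E ≥ 1 are reported but
flagged unreliable; the cut-off of one is the published reference value.

`similarity_top_k()` ranks reference profiles by cosine similarity
(Pearson available) in a vector space of reference-standardized
continuous features plus the dichotomized 0/1 categorical block — the
vector space is a package choice, stated here because no construction is
published. Zero-norm vectors get similarity 0; ties break by reference
order. `sp_majority()` takes the majority phenotype of the top k (k must
be odd). The similarity vote is advisory: it does not enter the final
diagnosis, which follows the printed three-module rule.

## The majority-wins diagnosis

`majority_diagnosis()` combines the three verdicts — forest label;
stratum (high → malignant, low → non-malignant, moderate →
intermediate); signature (MET/HMR → malignant, LMR → non-malignant,
MMR → intermediate) — with the marker override evaluated first: **any
MET signature forces a malignant diagnosis** regardless of the other
modules. Otherwise the majority of non-intermediate verdicts decides,
with two printed exceptions yielding "indeterminate, biopsy advised":
both risk modules intermediate, or two opposite verdicts plus an
intermediate one. The rule is total over all 2×3×4 verdict combinations
(exhaustively tested).

## Evaluation statistics

`performance_report()` computes the eight indices (Se, Sp, PPV, NPV,
LR+, LR−, F1, accuracy) from a confusion table, F1 being the harmonic
mean of sensitivity and PPV. Interval methods are package choices (none
are published): exact Clopper–Pearson for proportions, log-normal for
likelihood ratios, a seeded multinomial bootstrap for F1.
`roc_analysis()` uses the rank-statistic AUC (ties ½) with a DeLong
placement-variance interval and the max-Se/max-Sp optimal cut-point.
`prop_test_2x2()` is the two-sided equality-of-proportions test with the
Yates continuity correction — this exact procedure reproduces the
published cohort-comparison intervals to the printed precision, which is
how the correction choice was fixed. `wilcoxon_shift()` reports the
Hodges–Lehmann shift with its distribution-free interval.
`reproduce_table1()` re-runs the proportion test on all 33 packaged
count rows (group denominators 56 and 71 throughout, even for subset
rows) and checks every recomputed cell at tolerance 0.001; the printed
Wilcoxon rows need raw per-patient data and are therefore only
procedure-tested, not numerically matched.

## Missing values

`impute_missing()` fills continuous gaps by LASSO on the remaining 13
features (penalty by 5-fold cross-validation; glmnet's tie rule already
prefers the stronger penalty) followed by an OLS refit on the selected
support — the relaxed refit removes shrinkage bias, so an exactly
collinear reference is recovered to machine precision. Categorical gaps
take the predicted class of an rpart classification tree (a constant
reference column short-circuits to that constant). Imputing a feature of
"Necessary" or "Very high" priority attaches an explicit warning: the
prediction error is inflated when those features are absent.

## Numerical choices and problem sizes

Tolerances and sizes used by the test-suite and the verification script,
chosen as desk-scale defaults: generator calibration is checked at
n = 20 000 (AUC band 0.77–0.81, marker PPV band ±0.01 of the 0.912
closed form); prevalence is checked as the mean metastatic count over
200 cohorts of 237 against a binomial 99% band; coefficient recovery
uses 50 cohorts of n = 5000 with 999 bootstrap resamples and demands
per-coefficient coverage ≥ 0.90 for nominal 95% intervals; oracle
equivalences (threshold scan, ROC pair counting, Gini cut scan,
dichotomization lookup) are exact to 1e−12; the printed-table
regression uses tolerance 0.001 (printed rounding plus numeric slack).
Degenerate inputs are defined rather than rejected wherever the
workflow needs totality: single-class trees collapse to one labelled
leaf, zero-event proportion tests return p = 1 with a clamped interval,
all-tied rank tests return a flagged degenerate result, and
empty-denominator indices are NA with a flag.

## Known limitations

* Trained on synthetic cohorts, the models demonstrate correctness of
  the machinery, not clinical performance; the published headline
  accuracies are not reproducible without the clinical dataset.
* The original forest hyperparameters, regression coefficients, error
  model parameters (b0, b) and tree splits are unpublished; all are
  re-estimated, with the published thresholds and signature risks
  available as frozen inference constants.
* The generator makes no claim about inter-feature correlation beyond
  the size-feature pair, and the marker/importance inversion described
  above should be kept in mind when reading synthetic rankings.
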