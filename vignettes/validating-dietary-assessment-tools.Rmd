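---
title: "Validating automated dietary-assessment tools against weighed food records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating automated dietary-assessment tools against weighed food records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dieteval)
```

`dieteval` quantifies how faithfully an automated dietary-assessment tool
(a photo- or barcode-based food-record app) reproduces weighed food diaries,
the gold standard in which every ingredient of every record is weighed and
described. This vignette is the package's account of the underlying methods:
the models, their assumptions, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic-data tests do and do not show
about real data.

## Study structure and the food taxonomy

A *record* is one photographed dish/beverage or one scanned product; its
edible components are *segments*. Records fall into four types as a function
of reference segment count and the food/beverage flag: composite foods
(≥ 3 segments), simple foods (1–2), composite beverages (≥ 2) and simple
beverages (exactly 1). Every segment is labelled with a *food type*; types
nest in *food groups* which nest in *food categories*. The package ships a
synthetic 37-type / 23-group / 7-category taxonomy (`fixture_taxonomy()`),
whose group names follow conventional food-group nomenclature and whose
types and categories are invented; any study-specific taxonomy can be
supplied as a `type,group,category` CSV via `read_taxonomy()`.

Mixed segments (a gratin, a composed salad) are assigned by
`assign_mixed_segment()` to the food type of the ingredient with the highest
total calorific content, i.e. maximising weight × energy density. A
"highest calorific content" rule could also be read as highest energy
*density*; we implement total kcal, which is the reading that makes a
200 g potato portion dominate 50 g of cream in a gratin. Ties break by
larger weight, then lexicographically smallest label, making the rule
deterministic and order-independent.

## Segmentation

Reference segments detected by the tool are *found* (F), missed ones are
*omissions* (O), detections without a reference counterpart are *intrusions*
(I). All three are reported over the total number of true segments, so
%F + %O = 100 while %I is additional (intrusions are not a subset of the
reference segments and the three percentages may exceed 100 together).

**Half-width convention.** Proportions carry
`100 · 1.96 · sqrt(p(1−p)/(n−1))`. The `n−1` denominator arises when the
standard error is computed from the sample standard deviation of the 0/1
indicators; validation reports in this field print this form, and it is the
convention `proportion_halfwidth()` reproduces. It is a Wald-type
approximation: at p = 0 or 1 the half-width collapses to 0 and should be
read as "no variability observed", not as exact confidence bounds (the
classification module's Clopper–Pearson intervals are the exact ones).

**Linking.** Real validation studies link app to reference segments by hand.
`link_segments()` reproduces that workflow with a deterministic default plus
manual overrides: within each record, pairs are scored by taxonomy distance
(0 same type, 1 same group, 2 same category, 3 unrelated) plus a normalized
weight difference below 1 (weight only breaks taxonomy ties), and a pair is
linkable when its cost is ≤ 2. Among linkable pairs the package computes an
*exact* maximum matching (most links, then least total cost) by
branch-and-bound rather than a greedy pass: greedy matching is not optimal in
general, and per-record segment counts (≤ ~8) make the exact search cheap.
Records larger than 8×8 fall back to greedy. Canonical ordering by segment id
makes the result invariant to input row order.

## Classification

Found segments are graded exact (E: correct food type, or a synonym), close
(C: correct type but the naming is too generic, a slight product variant, or
overlooks an ingredient), far (F: wrong type, correct group) or mismatch
(M: wrong group). The close-match judgements are analyst-supplied flags, as
in manual coding — `grade_match()` only enforces the taxonomy logic, so a
type-correct pair with a close flag is C and without one is E.

Two chance-corrected coefficients summarise agreement:

* **Cohen's kappa** `(Po − Pe)/(1 − Pe)` with `Pe` from the marginal
  products, plus the standard large-sample SE. Cohen's kappa measures
  *reliability* and is sensitive to sparse or unbalanced marginals — single
  rare categories can move it substantially.
* **Uniform (Brennan–Prediger) kappa** `Ku = (q·Po − 1)/(q − 1)` with chance
  probability `1/q`. This is the *agreement* indicator: it depends only on
  the observed agreement rate and the number of categories. Its confidence
  interval is a seeded percentile bootstrap over the per-segment agreement
  indicators (B = 2000 by default); the bootstrap is our choice — interval
  conventions vary between reports and are rarely stated.

At type granularity both E and C count as agreement (both are type-correct
by definition); at group granularity E, C and F count. Because coding
practice can deviate from these definitions (e.g. a close match crossing a
food group when an overlooked ingredient changes the dominant component),
`run_pipeline()` reports the by-definition `Po` *and* the label-crosstab
diagonal `po_crosstab` side by side; at category level only the crosstab is
meaningful since mismatches may still share a category.

Per-group sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` come from
one-vs-rest collapses of the confusion table with exact Clopper–Pearson 95%
intervals (`stats::binom.test`); proportions are compared between strata
with Fisher's exact test (`stats::fisher.test`).

## Portion size

Weight error `est − true` is computed for exactly classified segments only —
using confused segments would penalise the tool twice for one classification
error. This is a framework choice the user can relax by passing E+C grades.
Summaries per type/group/category report mean weights, mean error, mean
absolute percentage error, the accuracy ratio (mean estimated / mean true
weight) and a paired t-test. There is no silent outlier rule: known
transcription errors are removed via an explicit exclusion list that is
echoed in the log, and segments with |error| > 500% are flagged, never
dropped.

## Energy and macronutrient agreement

Record-level nutrient totals of the tool (`y`) are regressed on the
gold-standard totals (`x`): `y = α + βx + ε`. Under the assumption that the
weighed diary is an unbiased gold standard with negligible measurement
error, α estimates the tool's differential bias and β its proportional bias;
this regression view is preferable to a Bland–Altman difference plot, which
is biased when one method is (nearly) error-free. Records with a true value
of 0 for a nutrient stay in the fit — they anchor the intercept, which is
exactly what makes the alcohol analysis informative.

**Variance model.** The residual SD is modelled as linear in the true value,
`σ(x) = s₀ + s₁x`, fitted by regressing absolute residuals on `x` and
scaling by `sqrt(π/2)` (the normality factor turning mean absolute deviation
into an SD). Linear SD is the simplest family that reproduces both stylised
facts of such tools — relative dispersion that *falls* with increasing true
quantity, yet a finite, non-zero coefficient of variation at `x = 0` — and
the interface is written so alternative families (power-of-x, exponential)
can be substituted. The fitted SD is floored at `1e-6 · max|y|` to keep
downstream quantities defined when residuals vanish; a warning fires when
the raw line is non-positive over more than 10% of the x range. Estimation
is single-pass (OLS, then the residual model) with no iterative
reweighting — a deliberate trade of a little efficiency for desk-scale
reproducibility.

The 95% limits of agreement are Wald-type with no transformation:
`(α + βx) ± 1.96·σ(x)`; their width is exactly `2·1.96·σ(x)`. For a nutrient
measured very noisily near zero the lower limit crosses zero — a diagnostic
of extremely poor agreement, not an error. Coefficients of variation
`Cv(x) = σ(x)/(α + βx)` are evaluated at the 25th/50th/75th percentiles of
the true values (linear-interpolation sample quantiles, chosen for
determinism) and averaged over records; records with a non-positive fitted
mean have no defined Cv and are excluded from the mean with a reported
count.

## The synthetic-study generator

`simulate_study()` produces paired reference/app record sets with the error
structure the analysis assumes, so that every stage is testable without
access to raw study data. Its defaults describe one fixed study design:

* **Design**: 63 composite foods, 63 simple foods, 30 composite beverages,
  33 simple beverages (189 records); 15 simple records entered by barcode
  scan. Segment counts per record: composite foods 3 + Poisson(0.15), simple
  foods 1 + Bernoulli(0.2), composite beverages 2 + Poisson(0.05), simple
  beverages 1 — expected total ≈ 368 segments. (Field data often code a
  blended drink as a single mixed segment, which would push composite
  beverages near one segment per record; the generator keeps the ≥ 2 floor
  of the record-type definition instead, at the price of slightly more
  beverage segments than a real study would count.)
* **Composition**: ~40 synthetic items with physiologic per-100 g values
  (`default_composition()`); reference nutrients are weight × per-100 g
  composition. Portion weights are log-normal around each item's typical
  weight (sdlog 0.3).
* **Error model** (`error_model()`): per-segment omission probability 0.02;
  per-record intrusion probability 5/189, realised as a spurious
  salad-dressing segment on photographed food records (the typical spurious
  detection); grade probabilities per record type chosen to mirror the
  observed difficulty ordering of such tools — composite foods
  (0.90/0.07/0.02/0.01 for E/C/F/M), simple foods (0.96/0.04/0/0),
  composite beverages (0.42/0.39/0/0.19 — beverages are hardest because
  milk, sugar and alcohol are invisible), simple beverages (0.94/0/0/0.06);
  multiplicative log-normal weight noise (sdlog 0.35, giving a mean absolute
  portion error around 30%) with geometric-mean bias factors above 1 for
  meat & poultry, fish & seafood, eggs & meat substitutes and potatoes/
  legumes (1.25/1.25/1.20/1.15), reproducing the overestimation pattern that
  propagates into a protein slope above 1; scanned records are error-free.
  An optional heavy-tail mixture (5% of segments at sdlog 0.9) reproduces
  occasional extreme individual errors (roughly −90% to +250%).

A far-match confusion needs a within-group sibling type with composition
data; where none exists the sampler degrades that draw to a mismatch (this
cannot occur for the default composite-beverage kernel, whose far-match
probability is zero).

**What passing tests show — and don't.** The generator draws items
independently, uses a single parametric noise family, knows nothing about
real dietary patterns, nutrient correlations beyond the composition table,
photography conditions, or database coverage. Green tests therefore certify
the *statistical machinery* — that each estimator recovers the parameters of
data generated under its own assumptions, and that the pipeline's
bookkeeping (linking, grading, aggregation) is exact — not that any
particular app performs well on real food.

## Test and verification design

Deterministic arithmetic is verified against published report-table cells
and independent oracles (exhaustive assignment enumeration for linking,
hypergeometric enumeration for Fisher's test, closed-form normal equations
for OLS, beta-quantile identities for Clopper–Pearson bounds). Stochastic
properties use fixed seeds and tolerances sized from sampling theory. Two
sizing choices deserve a note:

* The bias-parameter recovery check runs 200 replicates of a 189-record
  study with generator values α = 113.3, β = 0.6 and noise σ(x) = 10 +
  0.12x over log-normal true values (median ≈ 200 kcal). The noise scale
  was set from the closed-form heteroscedastic (sandwich) variance of the
  OLS estimators so that the design's own sampling error (~5–6% median
  relative error) sits well inside the 10% recovery bound — the test then
  certifies the estimator, not the luck of the draw.
* Limits-of-agreement coverage is checked empirically at n = 5000
  (tolerance ±2 percentage points around 95%), and end-to-end segmentation
  consistency averages 50 seeded studies (expected found rate
  ≈ 98% given the 2% omission rate diluted by error-free scans).

Problem sizes throughout (hundreds of segments per unit test, 50–200
replicates for Monte-Carlo checks, B = 2000 bootstrap draws) were chosen so
the full suite exercises every estimator at meaningful power while remaining
a desk-scale computation.

## Known limitations

* The automatic linker resolves ambiguity by taxonomy cost; records
  containing several same-type segments of similar weight can be linked
  differently than a human coder would, which is why ground-truth/manual
  links always take precedence.
* Cohen-kappa standard errors use the classical asymptotic formula; for
  very sparse groups (single-segment labels) they are optimistic, and the
  bootstrap interval on the uniform kappa is the more trustworthy summary.
* The linear-SD variance family is a documented stand-in for whatever
  variance-function estimation a given study used; when the true dispersion
  grows sub-linearly the Cv at the upper quartile will be biased upward.
* Energy-adjustment recalibration of tool estimates (using the fitted
  calibration to correct intakes) is out of scope.
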