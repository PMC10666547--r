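---
title: "Methods: direct classification of acute fish toxicity categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct classification of acute fish toxicity categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxprio)
```

## The problem

Regulatory prioritization of chemicals needs acute aquatic hazard
*categories*, not concentrations. The conventional route is a two-step
pipeline: a QSAR regression model predicts the 96 h LC50 (fathead minnow)
from molecular descriptors, and the prediction is then thresholded into a
category. `toxprio` implements that route alongside its competitor —
*direct classification*, a tree-ensemble classifier that maps descriptors
straight to the category — and the infrastructure both need: descriptor
curation, category schema construction, leverage-based applicability-domain
(AD) assessment, and evaluation reports.

The central claim the package lets you examine is that direct
classification avoids the error that regression injects at category
boundaries: a regression residual of half a log unit is harmless in the
middle of a category and fatal next to a threshold, whereas a classifier
optimizes the decision boundary itself.

## Descriptor curation

Descriptor calculators emit thousands of numeric features of mixed
reliability. `curate()` applies four filters in a fixed order, attributing
each removal to the first filter that triggers:

1. **Replicate stability** (`replicate_stability`). Descriptor calculation
   is repeated three times; a descriptor is dropped if, for any chemical,
   the spread across replicates exceeds `rel_tol` (default `1e-6`) relative
   to the largest magnitude, or `abs_tol` (`1e-9`) when all values are
   zero. This catches non-converged structure optimizations. The
   tolerances are not prescribed by any standard; the defaults treat
   anything beyond float-roundoff-scale differences as instability and are
   configurable.
2. **Missing values.** Descriptors with more than 10 % missing entries in
   the training table are dropped; remaining missing cells are imputed
   with the training-column median (deterministic and conservative).
3. **Max-scaling and variance filter.** Each column is divided by its
   maximum *absolute* training value (`fit_scaling`/`apply_scaling`), so
   training values land in [-1, 1]; the same training factors are applied
   to application sets, whose scaled values may exceed 1. We use the max
   absolute value rather than the plain maximum because a plain maximum
   flips signs or explodes magnitudes for negative-valued descriptors.
   `variance_filter` then keeps descriptors whose scaled sample variance
   (n − 1 denominator) is strictly below 0.1. Keeping the *low*-variance
   side is deliberate here — after max-scaling, honest count-like
   descriptors have small variance, while columns whose variance
   approaches the [-1, 1] limits are dominated by outliers or near-binary
   switching; the direction is nonetheless exposed as `keep = "below"` /
   `"above"` because the opposite convention (pruning near-constant
   columns) is also common.
4. **Cross-set ratio filter** (`ratio_filter`). A descriptor whose maximum
   magnitude in the application set exceeds 100 times its training scaling
   factor is unstable across sets and is removed from both. A zero
   training factor with any nonzero application value also triggers
   removal.

Curation is idempotent, and the curated application table always carries
exactly the curated training columns in the same order. `pca_scores`
(mean-centred PCA, two components by default) supports chemical-space
coverage plots.

## Toxicity category schemas

**GHS.** The fixed short-term (acute) aquatic hazard thresholds: acute 1
(LC50 ≤ 1 mg/L), acute 2 (1 < LC50 ≤ 10 mg/L), acute 3 (LC50 > 10 mg/L),
with boundaries inclusive on the more-toxic side. `assign_ghs` partitions
every positive concentration.

**Bootstrapped k-means** (`fit_kmeans_categorizer`). Four data-driven
categories in the (log10 LC50 mg/L, monoisotopic mass Da) plane:

* Both coordinates are z-standardized with the training split's mean and
  standard deviation before clustering — raw daltons would otherwise
  dominate the Euclidean metric. LC50 enters on the log10(mg/L) scale.
* The points are split 90/10; the training side is resampled with
  replacement 500 times, and each resample is clustered (k-means++
  seeding, 25 restarts, Lloyd iterations, tolerance `1e-6`, max 300
  iterations — all configurable).
* Centroid labels are aligned across iterations by sorting each set
  ascending by its log-LC50 coordinate (ties by mass), which makes "the
  most common centroid set" well defined despite label permutation.
* Aligned sets are rounded to 2 decimals (standardized units); the most
  frequent rounded set wins (frequency ties go to the earliest
  iteration), and the final centroids are the mean of the unrounded
  members of the winning class (`select_modal_centroids`).
* The lowest-log-LC50 centroid is always labelled "high toxicity".
* `holdout_agreement` reports the fraction of holdout points assigned
  identically by the modal centroids and by a single k-means fit to the
  full training split. It measures the stability of the bootstrap
  consensus — an operational stand-in for a "clustering accuracy", which
  is not otherwise defined for an unsupervised method.

Assignment (`assign_kmeans`) standardizes the query with the *stored*
training parameters and returns the nearest centroid's label; exact
distance ties go to the lower (more toxic) centroid index.

## The two predictors

Both models are random forests (via `ranger`), with per-tree feature
subsampling of ⌊√p⌋ variables.

* **Grid search** (`grid_search`): exhaustive over (number of trees,
  minimum leaf size), scored by 3-fold cross-validation — mean R² for
  regression, mean accuracy for classification. The regression grid
  defaults to 10 log-spaced tree counts in 100–1000 and leaf sizes 1–21
  in steps of 2; the classification grid to 20 steps over 200–2000 trees
  and 20 steps over 1–21 (17 unique integers after rounding). Score ties
  prefer fewer trees, then larger leaves.
* **Variable selection** (`select_by_relative_importance`): out-of-bag
  importances at the best cell are divided by the largest; variables
  contributing strictly more than 1 % are kept. Permutation importance is
  the default (impurity importance is available by configuration) because
  impurity importance is biased toward high-cardinality variables, and
  the permutation variant is the better-behaved out-of-bag quantity.
* **Final fit** (`fit_final`): refit on the full supplied data restricted
  to the selected variables, recording the training score and the
  out-of-bag score. The number of selected variables is whatever the 1 %
  rule yields for the data at hand, not a fixed target.
* **Two-step categorization** (`two_step_categorize`): 10^(predicted log
  LC50) pushed through the schema — GHS thresholds directly, or
  nearest-centroid assignment of (predicted log LC50, mass) for a k-means
  schema.

Every fit and every prediction takes an explicit seed and runs
single-threaded. The prediction seed matters: classification vote ties in
a random forest are broken randomly, and leaving that seed implicit makes
otherwise identical runs differ at tied chemicals.

## Applicability domain

The leverage of a query chemical with descriptor vector $x$ against the
training matrix $X$ (n × p, training-scaled) is

$$h = x^\top (X^\top X)^{-} x,$$

the hat-matrix diagonal for training rows. A chemical is in-domain when
$h \le h^*$; the default warning leverage is the Williams-plot convention
$h^* = 3p/n$, capped at 1.

When p ≥ n — e.g. the full curated descriptor space of a wide table —
$X^\top X$ is singular and $(X^\top X)^{-}$ is a Moore–Penrose generalized
inverse with singular-value cutoff (relative `rcond` `1e-10`,
configurable). Reports flag this regime explicitly: leverages there live
in the row space of the training set and the in/out decision is more
conservative than the full-rank geometry suggests. For full-rank
$X^\top X$ the generalized inverse equals the ordinary inverse, training
leverages lie in [0, 1], and they sum to rank(X) — properties the test
suite checks against a brute-force dense inverse.

`ad_assess` evaluates one descriptor subspace (full curated space,
regression-model variables, classification-model variables, or any named
subset); `ad_compare` tabulates in/out counts and pairwise flag agreement
across subspaces.

## Evaluation

`confusion` (rows = true, columns = predicted, misclassified = n − trace),
`r_squared` (1 − SSres/SStot), `pearson`, `residual_summary` (fraction of
residuals within ±1 log unit by default, plus quantiles), and
`agreement_fraction` between two label vectors. `compare_methods` bundles
these per method and reports the misclassification ratio relative to the
best method. Cross-validation R² is reported per fold; the median is the
headline summary, with the mean also available.

## The synthetic-data generator

Real training sets of this kind (hundreds of chemicals, thousands of
descriptors, pooled multi-source LC50s) cannot ship with a package, so
`generate_training` / `generate_application` emulate their structure:

* **Correlated descriptor blocks.** Descriptors load on a small number of
  latent factors (10 by default) plus small cross-loadings, so variable
  selection has redundancy and structure to find, as with real
  descriptors. Latent draws are heavy-tailed (t with 4 df, unit
  variance): real count/fragment descriptors are skewed and
  outlier-rich, which matters for max-scaling and the variance filter.
  Idiosyncratic descriptor noise is small (sd 0.05) — descriptors are
  computed quantities, not measurements.
* **Signal concentration.** Eight designated descriptors carry the
  response, with geometrically decaying weights (0.7^k). Observed
  importance profiles of descriptor-based toxicity models are strongly
  concentrated — a single logP-like variable can explain a third of the
  explained variance — and an equal-weight additive signal would be
  unrealistically rotation-symmetric and is also the hardest case for
  axis-aligned trees.
* **Responses.** `smooth`: a standardized sum of bounded ridge functions,
  located and mildly right-skewed so the log LC50 distribution spans
  roughly −3 to +5 log(mg/L). `discontinuous`: a weighted latent score is
  cut at empirical quantiles matching the configured mixture weights;
  each category contributes a Gaussian around its mean log LC50
  (defaults −0.5, 0.5, 1.5 — the centres of the two bounded GHS bins and
  the mirror position below the first threshold) with within-category
  spread 1.2 log units plus measurement noise (`noise_sd`, default 0.3).
  The spread is not a free dial: three category means can only reproduce
  the −3…+5 span of pooled experimental sets with on the order of a log
  unit of within-category scatter, and a hazard category does collapse a
  wide slice of the concentration scale. This is exactly the regime in
  which thresholding a regression output is fragile.
* **Masses.** Monoisotopic masses are near-uniform over `mass_range`
  (default 50–1000 Da) but correlated with a molecular-size latent
  factor, because mass is strongly descriptor-correlated in reality; with
  independent masses a k-means schema that uses mass would be partly
  unlearnable from descriptors alone and every schema-level comparison
  would be distorted.
* **Replicates.** Replicates 2 and 3 equal replicate 1 up to relative
  jitter of 1e-8, except for a configured fraction of descriptors
  (default 5 %) that receive 20–60 % jitter and should be caught by the
  stability filter.
* **Application sets.** Half the chemicals are drawn from the training
  distribution; half are shifted `shift_sd` training-sd units (default
  10) along a fixed random latent direction — a designed out-of-domain
  population for AD testing.

Everything is a pure function of the config, including its seed.

What the generator does *not* emulate: chemically valid structures,
descriptor semantics (no column "is" a logP), inter-descriptor constraints
(counts being integers, fingerprint bits), or a mass–toxicity
relationship. Passing tests on this generator show that the machinery is
correct and that the regression-vs-classification contrast behaves as
expected *under these structural assumptions*; they do not certify
accuracy on any real chemical inventory.

## Reproducibility and numerical choices

* Every stochastic operation takes an explicit integer seed; fits restore
  the caller's RNG state. An end-to-end `run_pipeline` run with a fixed
  config reproduces every output file bitwise, and its manifest records
  input/output md5 checksums and the config hash.
* Degenerate inputs fail loudly: zero scaling factors on retained
  columns, constant observed vectors in R², single-class CV folds,
  unknown labels in confusion matrices, column mismatches at prediction
  or leverage time.
* Tie-breaks are all deterministic and documented: grid-search score
  ties (fewer trees, larger leaves), modal-centroid frequency ties
  (earliest iteration), nearest-centroid distance ties (lower index),
  forest vote ties (seeded).

The test suite and the bundled analysis script run at reduced problem
sizes chosen to exercise every code path with stable statistics: the
end-to-end study uses 400 chemicals × 150 descriptors with 3 × 3
hyperparameter grids, the clustering fixture 400 points with 500 bootstrap
iterations, and the regression-versus-classification contrast 20
replicate studies of 800 chemicals × 100 descriptors at matched fixed
mid-grid hyperparameters (300 trees, minimum leaf 5) so both routes get
the same budget.

## Known limitations

* The leverage AD in the p ≥ n regime depends on the singular-value
  cutoff; two reasonable cutoffs can flag different borderline chemicals.
  Distance-based or density-based AD definitions are out of scope.
* The k-means schema inherits k-means' assumptions (convex, comparable
  clusters in the standardized plane); `holdout_agreement` measures
  consensus stability, not external validity of the categories.
* Grid-search cross-validation folds are not stratified by category;
  with rare categories and small n, fold construction can fail (by
  design, loudly) rather than silently rebalance.
* Median imputation ignores descriptor correlation; with the default
  10 % missingness cap the induced bias is limited, but heavily missing
  tables deserve a dedicated imputation strategy upstream.
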