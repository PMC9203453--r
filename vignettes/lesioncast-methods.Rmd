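---
title: "Methods: lesion occurrence, sparsity, and region-wise lesion estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion occurrence, sparsity, and region-wise lesion estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesioncast)
```

`lesioncast` estimates the presence of stroke lesions in brain atlas
regions from non-imaging clinical variables. This vignette is the
package's account of the model, its assumptions, the tunable parameters,
the synthetic-data generator, and the numerical conventions adopted
where the design was genuinely open.

## Lesion characteristics

A subject's imaging-derived profile is the vector of lesion degrees
$D_m \in [0, 100]$ (percent of region $m$'s voxels lesioned). A region
is *lesioned* when $D_m > 0$ strictly — any nonzero lesioned fraction
counts, so the binarization is scale-free.

Two summaries characterize a subject:

* **Occurrence**: the fraction of atlas regions lesioned.
* **Sparsity**: the average of the normalized inter-region distance
  $W_{mn}$ over unordered pairs where *both* regions are lesioned
  (mutual occurrence, AND logic). Pairs in which either region is
  intact are excluded from the average rather than contributing zeros;
  anything else would let intact tissue change the statistic. Subjects
  with fewer than two lesioned regions have no valid pair and are
  assigned sparsity 0, placing single-lesion patients in the
  low-sparsity corner of the (occurrence, sparsity) plane where they
  belong conceptually.

$W$ is built from region centroids: Euclidean distances, min-max
normalized over the off-diagonal entries so the closest region pair maps
to 0 and the farthest to 1. With a two-region atlas the single pair
makes min = max; the package returns 0 with a warning rather than
failing. Whether a voxel-level average distance uses all voxel pairs or
surface voxels only is a choice the centroid abstraction sidesteps;
for compact regions the orderings agree, and the registry CSV lets users
substitute their own coordinates.

The bundled registry (116 AAL region names → 18 lobes → 5 hemispheric
divisions) is a constructed stand-in: the hierarchy is a static
many-to-one table and the centroids are plausible synthetic coordinates,
shipped as `inst/extdata/aal116_registry_synthetic.csv`. Voxel-accurate
template mappings are deliberately out of scope.

## Patient stratification

`cluster_subjects()` runs k-means (k = 3, 10 random restarts, best
within-cluster sum of squares kept) on the raw (occurrence, sparsity)
points. No standardization is applied: both coordinates already live in
[0, 1], so there is no scale disparity to correct. Because k-means
labels are arbitrary, subsets are relabeled canonically by centroid
occurrence (subset 1 lowest, subset 3 highest), making "subset 2"
reproducible across seeds and machines.

## Subset prediction from non-imaging data

To use subset-specific models on patients without imaging, the subset
label itself must be predictable from clinical variables. The chain in
`train_subset_model()` is:

1. **Missingness filter** (`drop_sparse_features()`): features missing in
   more than 20% of subjects are dropped (threshold configurable);
   remaining gaps are median-imputed. The medians are stored so new
   subjects get the training treatment.
2. **Screening** (`screen_features_kw()`): Kruskal–Wallis across the
   three subsets at α = 0.05. Constant features have H = 0, p = 1.
3. **Reduction** (`reduce_dimensions()`): features are z-scored and the
   smallest leading set of principal components reaching 95% cumulative
   explained variance is kept. z-scoring is used because the batteries
   mix incommensurate scales (scores, doses, cell counts).
4. **Forest tuning** (`fit_subset_classifier()`): for each hyperparameter
   candidate (default grid: trees ∈ {100, 300}, depth ∈ {unlimited, 5,
   10}, mtry ∈ {√p, p}), 100 stratified 75/25 resamples are drawn; each
   training part is scored by stratified threefold cross-validation, and
   the candidate's quality is the mean multiclass MCC of the out-of-fold
   predictions. Ties in MCC break toward the higher correct rate. The
   winner is refit on all data.

The MCC uses Gorodkin's multiclass generalization, with the convention
that a degenerate marginal (all predictions in one class) scores 0.

## Region-wise lesion models

Each region's presence indicator is modeled with multivariate logistic
regression, $P = 1/(1 + e^{-(a_1 x_1 + \cdots + a_n x_n + b)})$, and
$P \ge 0.5$ is read as presence — the boundary goes to presence because
a screening application prefers false alarms over missed lesions.

Three variants are supported:

* `method = "none"`: maximum likelihood on features passing a Kendall
  τ-b screen against the binary outcome (p < 0.05, tie-corrected;
  constant features are excluded as τ is undefined for them).
* `method = "l1"` / `"l2"`: LASSO / Ridge on min-max-normalized features
  (constant features flagged and excluded). Normalization bounds are
  stored; new data outside the training range passes through un-clipped,
  which keeps the transform affine and honest about extrapolation.

**Nested cross-validation and resampling.** When a region has at least 4
presence subjects, the outer 4-fold assignment is re-randomized 100
times (the resampling unit is the whole fold assignment), giving
4 × 100 = 400 candidate models. Within each outer fold, 3 stratified
inner folds either tune λ (penalized; 20 values log-spaced over
[1e-4, 1e2], ties toward the stronger penalty) by mean inner-validation
sensitivity, or — for the unregularized variant — fit one model per
inner-training fold, record the best inner-validation sensitivity, and
refit on the full outer-training fold. Below 4 presences a single model
is fit on all data with no resampling. Sensitivity is the inner
criterion throughout because true-presence detection is the clinically
prioritized error direction.

**Selection.** Every candidate carries an AIC = 2k − 2 ln L computed on
its outer-training fit; the minimum-AIC candidate is selected, with ties
broken by fewer parameters, then by higher outer-validation sensitivity.
For penalized fits the log-likelihood is the *unpenalized* binomial
likelihood of the fitted coefficients and k counts the intercept plus
nonzero slopes — a documented convention, since AIC for penalized
estimators has no single standard definition (for Ridge this undercounts
the effective degrees of freedom; alternatives like trace-based df would
change AIC levels but rarely the within-region ranking).

**Degenerate fits.** Perfect separation would let ML coefficients
diverge; the package caps all coefficients at |a| ≤ 20 (a logistic
probability within 2·10⁻⁹ of saturation), flags the fit, and proceeds
deterministically. Fold assignments are stratified so classes appear in
every fold whenever counts permit; folds that still end up single-class
fall back to intercept-only fits rather than erroring mid-resampling.

## Resolution transfer

Fine-level (AAL) predictions transfer to lobes and hemispheric divisions
by OR logic: a coarse region is predicted lesioned exactly when any of
its constituent fine regions is ("modified estimation"). The coarse
ground truth is likewise the OR of binarized fine truth — not a
re-threshold of summed degrees — so a coarse region is truly lesioned
exactly when one or more of its members is. "Direct estimation" runs the
full modeling pipeline with each coarse region as the outcome;
`evaluate_pipeline()` compares the two by rank-sum tests on per-region
sensitivities, specificities and accuracies.

## Evaluation statistics

Per-region performance is accuracy, specificity and sensitivity from the
confusion counts, plus Fisher's exact two-sided association p. Ratios
with zero denominators (e.g. sensitivity in a region with no true
presence in a subset) are reported as missing and excluded from medians
— coding them 0 would bias the region-wise summaries downward. The
Kruskal–Wallis test is tie-corrected with H = 0, p = 1 for all-constant
input; its post hoc uses Tukey–Kramer comparisons on rank-transformed
data (the common "multcompare after KW" practice — a convention, not a
claim of exactness). The rank-sum z uses the tie-corrected normal
approximation without continuity correction, which makes z exactly
antisymmetric in the sample order. Spearman's ρ is computed with
asymptotic p-values; a constant vector yields missing values.

## The synthetic cohort generator

No patient-level dataset of this kind is publicly deposited, so the
generator is a first-class, tested module. Its defaults are the study
conditions the pipeline was designed around:

* subset sizes 67/86/42 (n = 195);
* subset 1: 1–3 spatially adjacent lesioned regions, 23 of 67 subjects
  with a single lesion; subset 2: 4–14 regions, moderate spread;
  subset 3: 15–37 regions, wide spread;
* degrees conditional on presence from 100 × Beta(0.8, 5) — right-skewed
  with mass near zero, so per-region medians sit below means and
  coefficients of variation are large;
* 250 features grouped under the standard battery names (BIT, CAT, MMSE,
  RBMT, TMT, BRS, FIM, apathy, HADS, JPSS, medication, metabolite,
  fundamental), 2 informative features per region shifted by ±2 baseline
  SDs in presence subjects, a weak shared severity factor (loading 0.3
  on 30% of features), metabolite features always pure noise, 5% values
  missing completely at random.

Spatial structure is planted by growing each subject's lesioned set from
a random seed region, choosing each next region among the few whose
inclusion keeps the running mean normalized distance closest to a target
drawn from the subset's sparsity range (0–0.15 / 0.18–0.36 / 0.40–0.50).
Targeting sparsity directly — rather than a pure distance-decay growth
rule — is what makes the planted geometry recoverable: with fully
overlapping subset-2/3 sparsity ranges, k-means cannot separate the
planted labels reliably, so the default ranges trim the overlap while
keeping each subset inside its intended band. Real cohorts do overlap;
recovery tests on the generator therefore show that the pipeline works
when the assumed structure is present, not that such structure exists in
any given clinic's data. Other idealizations to keep in mind: features
are Gaussian around family baselines (real scores are bounded and often
ordinal), missingness is MCAR (real missingness is informative), and
informative features act additively per region.

The generator exports its ground truth (planted subset per subject,
informative feature → region map with slopes) so recovery — clustering
ARI, screening recall and false-positive rate, coefficient sign
recovery — can be scored without reaching into generator internals.

## Reproducibility and problem sizes

Every stochastic step (cohort generation, fold assignment, resampling,
forest fitting and prediction) is driven by explicit seeds; running the
pipeline twice from the same configuration yields byte-identical JSON
reports. Forest predictions are seeded too, since majority votes can tie.

The test suite exercises the full candidate scheme (400 candidates at
n = 100 subjects and 20 features) once, and otherwise runs reduced
resampling (2–25 repetitions) on small atlases (8–20 regions) — the
properties under test (candidate counts, determinism, oracle equality,
recovery) do not depend on the repetition count. `scripts/acceptance.R`
runs the complete cohort at the default study conditions with 10
resampling repetitions per region model and the full 100-resample
classifier tuning; these desk-scale sizes are the package's chosen
defaults for a single-machine reproduction and are reported alongside
every quantity it writes.

## Known limitations

* Only lesion *presence* is estimated; degrees (lesion volume) are not
  modeled — the right-skewed degree distributions that motivate
  binarization also make degree regression ill-posed at these sample
  sizes.
* Performance is evaluated on the fitting cohort (as the nested CV's
  outer validation guards optimism only partially); a held-out cohort
  evaluation is the user's responsibility.
* The bundled atlas hierarchy and centroids are synthetic stand-ins;
  template-accurate region geometry must be supplied by the user for
  anatomical interpretation.
* AIC for penalized fits uses the nonzero-coefficient parameter count —
  a convention, with the caveats noted above.
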