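---
title: "Sparse PLS-DA biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PLS-DA biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortSPLS)
```

# Scope

`cohortSPLS` implements a complete discovery analysis for small
case-control cohorts with wide, block-structured numeric predictor tables
and a binary endpoint (the motivating application is subclinical
atherosclerotic plaque in healthy elderly participants). This vignette is
the package's own account of the statistical machinery: the models and
their assumptions, every tunable parameter that matters, what the
synthetic-cohort generator does and does not emulate, the numerical
choices, and the design decisions taken where the procedure was genuinely
open.

# The synthetic cohort generator

Real cohorts of this kind are not freely redistributable, so the package
ships a generator whose defaults are the study conditions the analysis
targets: `nSamples = 79` with a fixed 29 cases (prevalence 29/79, class
sizes are deterministic, not Bernoulli-sampled, so stratified folds are
reproducible), `nFeatures = 148` split over seven measurement blocks
(30 cell percentages, 38 serum proteins, 20 gene-expression levels,
15 vascular, 10 anthropometric, 10 activity, 25 nutrition items),
`missingRate = 0.038`, `outlierCellFraction = 0.005` with displacements of
4–8 column SDs, and `nInformative = 10` planted biomarkers at a
standardized effect of `effectSize = 1` SD with recorded random signs.

Within a block, every column loads on one shared latent factor with
`withinBlockCorrelation = 0.2`; block location/scale centres are drawn
per column within ±50% of block-typical values (percentages are clamped to
[0, 100]). The values 0.2 and the block scales are the package's choice of
a realistic weak-to-moderate within-panel correlation; they are fixed
defaults, not fitted quantities.

Missing cells are deleted *missing at random*: the deletion probability of
a cell is `plogis(a + z)` where `z` is the standardized value of the
block's designated driver column (the first column of each block, itself
never deleted) and `a` is calibrated by root-finding so the expected
overall rate matches the target. The mechanism therefore depends only on
always-observed values — regressing the missingness indicator on the
hidden deleted values shows no association (property-tested) — while
missingness still concentrates in rows with high driver values, which is
what makes multivariate imputation beat column means.

What the generator does **not** emulate: real marker co-expression biology
(correlation is exchangeable within a block), longitudinal structure,
non-numeric covariates, heavy-tailed measurement error beyond the injected
point outliers, and block-specific missingness rates. Passing recovery
tests on these cohorts therefore demonstrates that the pipeline's
machinery works under its stated assumptions, not that it would attain the
same error rates on any particular real cohort.

# Preprocessing

## Imputation-method selection

Eight candidates are scored per column: `mean`, `median`, `knn` (mean of
the `k = 5` nearest rows by Euclidean distance over mutually observed
coordinates, distance scaled by the number of shared coordinates),
four chained-equation variants, and `stochastic_regression` (one linear
regression on the complete columns plus seeded Gaussian noise with the
residual SD). The chained variants initialize missing cells at column
means and run exactly `sweeps = 10` full sweeps in order of increasing
column missingness, refitting their regressor of each incomplete column on
all other columns and overwriting its missing cells; only the final
completed dataset is used. The regressor families are ordinary least
squares (`chained_linear`), ridge (`chained_bayes_shrinkage`,
`ridgeLambda = 1`, a deliberate, substantial shrinkage because the design
is wider than it is tall: p ≈ 2n), random forest (`chained_forest`,
100 trees, single-threaded for determinism) and gradient boosting
(`chained_boosted`, 50 rounds, depth 3). These four families preserve the
structure of a practitioner's chained-imputation suite without binding the
package to any specific external implementation.

Each incomplete column keeps the candidate maximizing the AUC of a
univariate logistic regression of the outcome on the completed column.
The AUC is evaluated in-sample on the full cohort — a faithful but
optimistic choice, made deliberately because the selection happens before
any cross-validation; the imputation choice is *not* re-tuned inside CV
folds (nesting it would multiply the cost of the protocol roughly eightfold
for a selection step whose candidates rarely differ downstream). Exact AUC
ties resolve by a fixed, reported tie order (the candidate list order by
default).

## Outliers and transforms

Outlier detection is Tukey's fence rule: `Q1 − m·IQR` and `Q3 + m·IQR`
with `fenceMultiplier m = 1.5` and quartiles by linear interpolation
between order statistics (R quantile type 7). The rule is applied to
observed cells only; missing cells are never flagged, and columns with
fewer than four observed values are skipped with a warning. Flagged cells
are replaced by independent seeded Uniform(lower, upper) draws, so a second
detection pass against the same fences is clean by construction.

Two monotone log transforms are provided. `log_shift` is
`x ↦ log(x + 10⁻⁵)` and requires `x > −10⁻⁵`. `log_scaled` is
`x ↦ log(a·x′ + c)` where `x′ = x − min(x)` if the column contains
non-positive values (the offset maps the minimum to zero, which stays in
the transform's domain — the simplest treatment of negatives that keeps
the spec reusable on held-out data) and `x′ = x` otherwise; `c` is the
smallest strictly positive value of `x′` and `a = 1/c`, so `a·c = 1` and
the smallest positive value maps to `log(2c) > log(c)`. The pipeline's
default is `log_scaled` for every column, the transform under which the
final model is fitted; whether originally complete columns should also be
transformed is not dictated by the procedure, and the package transforms
all columns uniformly for scale coherence.

# The univariate screen

Per variable, Shapiro–Wilk within each outcome group routes to one-way
ANOVA (all groups compatible with normality at `alphaNormality = 0.05`,
configurable) or Kruskal–Wallis otherwise; a constant group counts as
non-normal. Post-hoc comparisons use Dunn's tie-corrected rank z tests
with Holm adjustment (no suitable Dunn implementation ships with the
pre-installed stack, so the z statistic is computed directly from rank
sums) or Tukey's HSD with its native familywise adjustment. The univariate
logistic fit is unpenalized IRLS (`glm`, tolerance 1e-8, 100 iterations);
perfect separation is detected either by the fitted-probability warning or
by a diverged slope and is flagged, with the slope capped at ±20 per SD of
the predictor. Screen p-values are reported unadjusted, matching common
Table-1 practice; family-wise correction across the 148 variables is
intentionally out of scope.

# Sparse PLS-DA

## Fitting

Predictors are centered and scaled to unit SD (constant columns get scale
1, carry zero weight throughout, and keep their index so reports stay
aligned — they are flagged, not dropped). The outcome becomes a centered,
scaled two-column one-hot dummy. Per component, the penalised-SVD
iteration alternates a soft-thresholded update of the x-loading `u` (the
threshold is the (keepX+1)-th largest absolute entry of `Mv`, so exactly
keepX loadings survive for generic weights) with a normalized update of
the y-loading `v`, starting from the leading right singular vector of
`M = XᵀY`, until the loading change is below 1e-9 or 500 iterations
(non-convergence warns with the iteration count; in practice two to five
iterations suffice because `M` has only two columns). Deflation is
regression-mode on both `X` and `Y`, which yields the `q` vectors needed
for dummy-space prediction.

One degenerate case deserves note: after a `keepX = 1` component, the
selected column deflates to exactly zero, so a later full-density
component has one structurally zero weight. This is correct behaviour
(the variable has no residual variance to contribute), and the "exactly
keepX nonzeros" invariant is property-tested away from this non-generic
configuration.

The sign of each component is fixed by `cor(t_h, case dummy) ≥ 0`. The
orientation rule itself is a package convention; what matters
scientifically is only the resulting interpretation — case-enriched
variables load positive, case-depleted ones negative — which the
convention pins down deterministically.

## Prediction and metrics

`max` assigns the class with the largest de-scaled predicted dummy value;
`centroid` and `mahalanobis` assign the nearest training class centroid in
score space, the latter under the pooled within-class score covariance
(the within-class pooling is the package's choice where the distance's
covariance is unspecified; a singular covariance falls back to centroid
with a warning). BER is the unweighted mean of per-class error rates; AUC
is the rank formulation with half-credit ties, and both are verified
against exhaustive enumeration oracles in the tests.

## Cross-validated tuning

The protocol is stratified 10-fold cross-validation repeated 100 times
(`folds`, `reps`), with fold membership re-randomized every repetition and
per-class round-robin assignment that also balances total fold sizes. All
preprocessing that the model learns (centering/scaling) is refit inside
each training fold; held-out rows never touch the fit. BER is aggregated
per repetition from the pooled out-of-fold predictions (SDs are across
repetitions) — pooling before averaging keeps every sample's weight equal
under uneven fold sizes.

Stage 1 fixes the component count and distance: a dense model at up to
`ncompMax = 4` components is cross-validated under all three distances,
and the pair minimising mean BER wins, with ties resolved to fewer
components and then to the order max < centroid < mahalanobis. Stage 2
tunes keepX sequentially per component over the grid
`{5, 10, 20, 40, 80, 120, 140, p}` (chosen to span the usual tuning-curve
range on a 148-predictor table): the lowest-mean-BER candidate is the
benchmark, and the chosen value is the *smallest* candidate whose paired
one-sided t-test against the benchmark is non-significant at
`alpha = 0.05` — parsimony unless demonstrably worse. On pure noise no
candidate beats any other and the smallest survives, which the tests
assert.

# The relevance network

Variable–class similarity is `Σ_h cor(X_j, t_h)·cor(Y_k, t_h)` over the
fitted components (scaled training column, centered class dummy), and
variable–variable similarity replaces the class profile with the second
variable's correlation profile. This correlation-product form is the
standard relevance-association measure for PLS-family latent-variable
models; because the two centered class dummies are exact negatives of one
another, variable–class similarities are antisymmetric across the two
class nodes (tested to 1e-12). Edges require `|similarity| ≥ 0.23` (the
display threshold of the motivating analysis); isolated nodes remain in
the node table. The top-k table is ordered by absolute similarity to the
case class with alphabetical tie-breaks, and also reports the plain
Pearson correlation of each variable with the case indicator, since a
reader comparing against a published network cannot always tell which of
the two an "r" value denotes.

# Pipeline, determinism and problem sizes

`runPipeline()` executes: load/simulate → imputation selection → outlier
treatment → transform → univariate screen → tuning → final fit on the full
preprocessed cohort with the tuned hyperparameters (a single final model,
refit on all samples) → loading ranking → relevance network. Every random
draw derives from the master seed through labelled child seeds, so
identical configurations produce byte-identical `report.json` files; this
is asserted in the tests.

The shipped tests and the acceptance script run the full protocol at
reduced simulation sizes chosen by the package — e.g. 5 CV repetitions
instead of 100, a 6-point keepX grid, 20 generator seeds for recovery
rates, and the lighter half of the imputation suite inside the end-to-end
pipeline runs (the chained tree-based candidates are exercised in their
own dedicated simulations) — sizes at which every qualitative conclusion
(chance-level permutation BER, near-zero separable BER, ≥7/10 planted
biomarkers recovered, chained imputation preferred for predictable
columns) is already stable across seeds.

# Known limitations

* Only two-class outcomes are tested; the machinery is structurally
  multi-class but unvalidated beyond K = 2.
* Imputation AUC selection is in-sample and therefore optimistic; it
  selects a method, not an error estimate.
* Multiple-imputation pooling (Rubin's rules) is out of scope — the
  chained methods return one completed dataset.
* The generator's exchangeable within-block correlation understates the
  structured co-expression of real immunological panels, so real-data
  keepX choices will likely differ from synthetic ones.
* The permutation-null and recovery guarantees are statements about the
  generator's conditions (79 × 148, MAR at 3.8%, effects of 1 SD), not
  about arbitrary cohorts.
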