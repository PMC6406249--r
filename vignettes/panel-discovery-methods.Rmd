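---
title: "Methods: gene-panel discovery and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-panel discovery and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemopanel)
```

## The model

`chemopanel()` treats panel discovery as wrapper feature selection around a
three-class classifier. The training data are a genes × samples expression
matrix for a small set of cell lines and one scalar drug-efficacy summary
per line, the *activity area* of its dose-response curve (larger = more
sensitive). The procedure:

1. **Tertile response groups.** Lines are sorted by ascending activity
   area and cut into three near-equal ordinal groups, low < medium < high.
   Group sizes are `floor(n/3)` with the remainder assigned one-per-group
   starting from the low group, so 25 lines split 9/8/8. The cut is a rank
   rule: the activity-area values at the boundaries are data realizations,
   not parameters. Ties are broken by input order so the assignment is
   deterministic.
2. **Univariate screen.** Each gene is tested by a Kruskal-Wallis rank
   test across the three groups (chi-square approximation, 2 df, tie
   corrected); genes with p below `alpha` (default 0.01) form the
   candidate pool. The screen is rank-based, so it is indifferent to
   monotone transformations of the expression scale — which is also why we
   make no assumption about whether the input intensities are logged.
3. **GA wrapper selection.** The panel is the `panel_size`-subset of the
   pool (default 10) maximizing leave-one-out cross-validated accuracy of
   the classifier. Exhaustive search is hopeless — for a 575-gene pool
   there are about 1.01 × 10²¹ ten-gene subsets
   (`panel_search_space(575, 10)`) — so a seeded genetic algorithm
   searches instead.
4. **Final model.** The SVM is refit on all samples restricted to the
   selected panel. The object stores the panel, its LOOCV accuracy, the
   per-gene training mean/sd, and the standardized training submatrix
   (used by the cohort simulator).

### Classifier

The classifier behind both fitness and the final model is a support vector
machine with one-vs-one multiclass reduction (`e1071::svm`). Defaults are
a linear kernel with cost C = 1: with ~25 samples and 10 standardized
features, a linear boundary is the smallest-assumption choice, and C = 1
is the conventional default when features are on a common (z) scale. Both
are configurable through `svm_control()`; nothing in the pipeline depends
on the linear choice.

### Genetic algorithm

Individuals are gene subsets of exactly `panel_size` distinct genes.
Operators (all configurable via `ga_control()`):

* population 100, generations 10 — the fitness trajectory plateaus well
  before generation 10 at the intended problem scale, which is why 10 is
  the default stopping point;
* fitness-proportional (roulette) parent selection;
* single-point crossover on the gene list (rate 0.8), followed by repair:
  duplicate genes introduced by crossover are replaced with uniform draws
  from the unused pool;
* per-position mutation (rate 0.05) swapping a gene for an unused one;
* elitism 1, plus a *global elitist memory*: the returned panel is the
  best individual ever evaluated, so the best-so-far fitness is
  non-decreasing by construction.

Fitness evaluations are memoized by subset, and the whole run is a pure
function of `rng_seed`. These operator choices are the package's own
design; the search problem is robust to them in the sense that any
configuration with elitist memory and a reproducible stream satisfies the
same contracts the tests check (monotone best-so-far fitness, determinism,
improvement over the initial generation).

### Permutation significance

`permutation_test()` draws `n_trials` random `panel_size`-subsets
(independently per trial, so subsets may recur), scores each by the same
LOOCV metric, and reports `empirical_p = n_success / n_trials`, the
fraction reaching the observed accuracy. Two nulls are meaningful and both
are supported via the `pool` argument:

* **Screened-pool null** (pipeline default): draws from the
  Kruskal-Wallis-significant genes. This asks whether the *GA* adds value
  beyond the screen. When the screen is very stringent and the signal
  strong, the pool itself is so enriched that random subsets also classify
  perfectly and the empirical p is large — visible on the strongly
  separable synthetic fixture.
* **Full-array null**: draws from all genes, asking how often a random
  panel of the same size matches the observed accuracy by chance alone.

We read the published protocol as using the same evaluation metric (LOOCV
accuracy) in the permutation trials as in the GA; resubstitution accuracy
would make the null easier to beat, so the LOOCV reading is the
conservative one.

## Transfer to patient cohorts

`predict()`/`classify_cohort()` restricts a cohort matrix to the panel
genes, standardizes, and predicts a group per patient. The default
standardization is **cohort-wide**: each panel gene is z-scored with the
cohort's own mean and sd. This is what makes the panel portable across
platforms — any positive per-gene affine map of the cohort matrix (gain,
offset, unit change) leaves predictions identical, a property the tests
assert exactly. The cost is an assumption: the cohort's group composition
should be broadly comparable to training, because heavy imbalance shifts
the cohort mean and hence the z-scores. `standardize = "training"` applies
the stored training mean/sd instead, appropriate when cohort and training
share one platform.

Survival analysis is delegated to the survival package: Kaplan-Meier
product-limit curves (`km_curve()`), the two-sided log-rank test
(`logrank_test()`), and Cox proportional-hazards models (`cox_fit()`,
Efron tie handling, Wald confidence intervals). `filter_cohort()` applies
the treated-and-survived-beyond-30-days rule (strict inequality: a patient
surviving exactly 30 days is excluded) before any survival comparison.
The panel enters Cox models as a binary term (`panel_term()`): medium+high
versus low by default, mirroring how a minority-high cohort is usually
reported; high versus low (medium set to `NA`) for extreme-group
comparisons and KM display. `schoenfeld_sample_size()` implements the
closed-form events formula
E = (z₁₋α/₂ + z_power)² / (p(1−p)(ln HR)²), divided by the overall event
probability and ceiling-rounded; with HR 0.52, α 0.05, power 0.70, events
near-certain and p 0.776 it plans 84 patients.

## The synthetic-data generators

`gen_cell_line_dataset()` emulates the discovery input: by default 25 cell
lines, 2000 genes, a continuous (almost surely tie-free) uniform activity
area, and 10 planted signal genes at randomly chosen rows whose group
means sit at −e, 0, +e (in units of the noise sd, default effect e = 3)
for the low/medium/high tertiles; all other genes are independent of
response. Noise is Gaussian on a positive baseline (mean 8, a log2-like
microarray scale) so coefficient-of-variation probe collapse is well
defined. Defaults mirror the intended study scale; the 3-sd effect makes
the planted genes reliably detectable at α = 0.01, which the power test
verifies across seeds.

`gen_cohort()` emulates a validation cohort from a fitted model: patient
groups are drawn with configurable proportions (default 60/25/15
low/medium/high — high responders a minority, as in real cohorts), panel
expression is drawn from per-gene Gaussians matching the model's
group-conditional training means (pooled within-group sd) and mapped back
to the training measurement scale, survival is exponential with
group-specific hazards (low-group hazard 0.03 per time unit, hazard ratios
0.7/0.52 for medium/high by default) and censoring is independent
exponential calibrated so each patient is censored with exactly the
requested probability. Clinical covariates (residual tumor, FIGO stage,
grade, histology) are drawn independently of survival, so they are pure
noise covariates in Cox fits.

What the generators do *not* emulate: probe-level artifacts (GC bias,
batch structure), heavy-tailed or log-normal expression noise,
non-proportional hazards, informative censoring, and covariates genuinely
confounded with response. Passing tests therefore demonstrate the
machinery is correct under the model's own assumptions, not that any
particular clinical dataset will validate.

## Numerical choices and degenerate inputs

* Standard deviations use denominator *n − 1* everywhere (screen-scale
  CVs, z-scoring, stored training stats) — consistent at the small sample
  sizes the method targets.
* Quantile normalization averages tied ranks (the `ties = TRUE` dialect of
  `limma::normalizeQuantiles`); the operation is idempotent and makes
  sorted columns bit-identical on tie-free data.
* Coefficients of variation are computed on the post-normalization
  intensity scale (normalization precedes collapse in the pipeline
  ordering); a probe with non-positive mean is an error rather than a
  silent NaN.
* Constant genes are surfaced as errors naming the gene; `drop_constant`
  converts the error into a logged drop. The same applies to panel genes
  constant in a prediction cohort.
* The Kruskal-Wallis chi-square approximation is *conservative* at n = 25
  with 9/8/8 groups: its true type-I level at nominal α = 0.01 is near
  0.6%, a fact the calibration test measures against a rank-permutation
  oracle rather than assuming the nominal level. No exact enumeration is
  attempted — group sizes 9/8/8 put the exact null far beyond reach, and
  the screen is a filter, not an inference.
* LOOCV accuracy under label permutation is slightly *below* the
  largest-group proportion (removing a sample of class g tilts the
  training set away from g) — the familiar pessimistic bias of
  leave-one-out under a null. The no-leakage test is therefore one-sided:
  mean permuted-label accuracy must not exceed chance plus noise.
* Cox fits reject single-level covariates and abort, with a diagnostic, on
  warnings that signal monotone-likelihood separation or non-convergence.

## Test problem sizes

The suite exercises the pipeline at sizes chosen to make every property
checkable in seconds: a 25 × 50 separable fixture for GA recovery (the
screen shrinks its pool to roughly the planted genes, so recovery of ≥8 of
10 planted genes plus perfect LOOCV accuracy is the expected outcome), a
12-gene / 12-sample fixture whose 66 possible panels are exhaustively
enumerated as the reference for the Monte-Carlo permutation estimate, 1000
replicates for log-rank null calibration, and 100 replicates of n = 300
cohorts for recovery of a planted high-vs-low hazard ratio of 0.52.
Oracles are re-derived from first principles in the test helpers (rank
statistic, product-limit risk sets, brute-force CV collapse) and never
share code with the implementation.

## Known limitations

* The panel size K is user-fixed, not internally optimized; the method's
  premise is that a fixed, assayable K is wanted.
* Single-drug, single-endpoint training; no multi-drug joint modelling.
* Cohort-wide z-scoring assumes comparable group composition between
  training and cohort (see above).
* Survival validation assumes proportional hazards and non-informative
  censoring; `cox_fit()` does not test the proportionality assumption.
* The permutation p-value is Monte-Carlo: its standard error is
  `sqrt(p(1-p)/n_trials)`, so very small p-values need very many trials.
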