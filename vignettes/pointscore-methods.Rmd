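---
title: "How pointscore derives and validates point-based risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How pointscore derives and validates point-based risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter and why their defaults are what they
are, what the synthetic generator does and does not emulate, the numerical
conventions, and the design choices that were genuinely open.

## The model

A point-based risk score is a deliberately restricted prediction model: a
small set of variables, each partitioned into a few categories, each
category assigned a small nonnegative integer, the per-episode total being
the risk statement. The statistical engine underneath is a multivariable
logistic regression on category indicators,

    logit P(Y = 1) = beta_0 + sum_v sum_c beta_{v,c} * 1[X_v in c],

followed by a deterministic discretisation of the coefficient vector:
re-reference each variable at its lowest-coefficient category and refit (so
all coefficients are nonnegative), divide by the smallest positive
coefficient (`beta_lowest`), and round. The score is therefore a monotone
affine image of the fitted linear predictor, degraded only by rounding.
Two consequences are used as test oracles:

* before rounding, the normalised score has *exactly* the linear
  predictor's AUC (per-variable reference shifts change the total by a
  constant; division by a positive scalar is strictly monotone) — the suite
  asserts equality to 1e-12;
* after rounding, the AUC loss is bounded in practice; the suite guards it
  at 0.02 on synthetic cohorts of n = 5,000.

The working assumptions are those of every categorical main-effects model:
effects are additive on the log-odds scale across variables, constant
within a category, and the outcome is a fixed binary label per episode.
Non-linearity in a continuous predictor is captured only through the bands
(which is why U-shaped physiology such as temperature or blood pressure
works), interactions not at all.

## Pipeline stages and their parameters

**Splitting** (`split_cohort`): 70/10/20 train/validation/test, simple
random by default. An outcome-stratified mode exists (`stratify = TRUE`)
for small cohorts where a plain split can starve a partition of events, but
it is off by default to match the plain-random convention of cohort
studies. The test partition enters only the final evaluation; the suite
checks that perturbing test rows changes neither ranking, parsimony curve
nor score table.

**Cleaning** (`flag_outliers`, `impute_from_training`): values outside
user-supplied plausibility ranges become missing; ranges live in a config
file because they are domain knowledge, not data. Continuous missing cells
are filled with the *training* median (mean of the two central order
statistics for even counts — the conventional definition); categorical
missing cells become an explicit `Unknown` category, on the reasoning that
in categorised models a missing-indicator level uses all available
information and can itself carry points.

**Ranking** (`rank_variables`): a classification random forest with
`ntree = 100`, `mtry = floor(sqrt(p))`, trees grown to maximal size on
bootstrap samples. Importance is raw mean decrease in Gini impurity; it is
not normalised because only the order is consumed downstream. Ties are
broken by variable name so the ranking is deterministic. Categorical
predictors are integer-coded by training outcome rate before fitting,
which keeps the split search binary and the encoding reproducible. The
forest's bootstrap is keyed by row index, so importances are reproducible
for a fixed seed but only the *order* (not the values) is stable under row
permutation; the tests assert exactly that.

**Transformation** (`quantile_grid`, `derive_cutoffs`): percentiles
`k = (5, 20, 80, 95)` with `K = 5`. Percentile convention is linear
interpolation between order statistics (R type 7) — the method never
states one, and this choice is continuous in the data. Duplicate quantiles
(heavily tied labs) collapse, reducing the category count instead of
erroring; `K` is a maximum, not a promise. Bins are left-closed and
right-open, the bottom bin open below, the top bin unbounded above, so a
value equal to a cutoff lands in the upper band; interval labels print this
convention (`"a-b"` is `a <= x < b`). Cutoffs are carried at full floating
precision; human-readable rounding belongs to the fine-tuning pass
(`fine_tune_cutoffs`), after which stages 2–3 are simply re-run. Quantiles
are derived from the training partition only, consistent with the training
set being the sole source of the score.

**Weighting** (`fit_weights`, `relevel_references`, `derive_points`): the
logistic fit carries a small ridge penalty, lambda = 1e-4 on non-intercept
coefficients, implemented as penalised IRLS. The penalty exists purely to
keep estimates finite when a category has zero events (quasi-separation);
at this magnitude it is invisible on well-conditioned data (the suite
checks agreement with `glm` to 1e-3 on a 2x2 design whose log odds ratio is
ln 16). A separation flag is raised when any |beta| exceeds 10. The second
pass is a genuine refit, not a re-parameterisation; any residual negative
coefficient (possible in finite samples) is clamped to zero with a warning.
`beta_lowest` excludes coefficients at or below eps = 1e-6 to avoid
dividing by a numerical zero. Rounding is half away from zero (2.5 becomes
3), the convention of hand-computed clinical scores; base R's half-to-even
would be surprising here. One honest caveat: dividing by the smallest
positive coefficient means a single near-zero but positive category
inflates every point value. The method inherits this from its design; the
optional ceiling normalisation (`normalize_to_ceiling`, off by default
since it is a presentation choice) is the practical remedy, and the ceiling
must be at least the number of variables so points do not collapse
together.

**Selection** (`parsimony_curve`, `select_m`): the curve evaluates the
*integer* score on the validation set, since the deployed object is the
integer score, not the logistic predictor. The automatic rule — smallest
`m` whose gain to every larger evaluated `m` is below `delta = 0.005` — is
an operationalisation of "the plateau"; the method's intended usage is a
human reading the plot, so manual `m` is a first-class argument. The rule
is monotone in `delta` (tested). The default grid is `1..min(20, p)`. With
small validation sets (a few hundred events or fewer) the curve is noisy
and the automatic rule can overshoot; that is a property of the rule, not a
bug, and the manual mode is the answer.

**Evaluation** (`evaluate_scores`): AUC by midrank statistic (equals
trapezoidal ROC area; ties count half). The optimal threshold minimises
Euclidean distance to the ROC upper-left corner with ties resolved to the
lowest threshold; "about 95% sensitivity/specificity" rows use the
conservative extreme threshold still reaching the level, since exact
levels are unattainable on integer scores. The positivity rule is globally
"positive iff score >= threshold" — with integer scores the convention is
consequential, so it is stated in the report. Bootstrap CIs are percentile
2.5/97.5 over 1,000 episode resamples by default (the replicate count and
CI method are stated defaults, not claims of optimality); replicates
missing a class are redrawn. Calibration is reported as observed event
rates over score intervals (left-closed bins, last bin closed so the edges
cover the data); undefined ratios (empty bins, zero denominators) are NA,
never 0.

## The synthetic cohort generator

`default_ehr_spec()` emulates a first-day adult-ICU table: nine signal
variables (age, heart rate, respiration rate, systolic blood pressure,
temperature, SpO2, platelet, BUN, lactate) with normal or log-normal
marginals matched to typical published cohort medians/IQRs, ten pure-noise
labs/vitals, and two categorical confounders (sex, insurance). The outcome
is drawn from a logistic link on the true integer total with slope 0.08
per point, and the intercept is calibrated by bisection (on a fixed
50,000-draw sample of true totals) to a 9% event prevalence, typical of
inpatient mortality in adult ICU cohorts.

Two generator design choices deserve justification:

* **True cutoffs sit near marginal quintiles, not at the 5/20/80/95
  grid.** Parameter recovery compares estimated category coefficients;
  their standard errors scale like `1/sqrt(n_cell * p * (1-p))`. Quintile
  cells keep every cell large (about 4,000 episodes at n = 20,000), so
  recovery is a property of the estimator rather than of cell-size luck.
* **True points are distinct within each variable with pairwise gaps of
  about five.** Rank-recovery of category points is only well posed when
  adjacent effects are separated by several estimation SEs; with exact
  ties or one-point gaps the recovered order is a coin flip for any
  estimator. These values were fixed at design time and are not tuned.

What the generator does *not* emulate: correlation between labs and vitals
(all predictors are independent), informative missingness (missingness is
MCAR only), longitudinal structure, and measurement error. Passing the
recovery and ranking tests therefore shows the pipeline recovers additive
categorical truth at realistic prevalence and scale — it does not show
robustness to collinearity or informative absence, which real EHR data
have.

## Problem sizes and determinism

The validation studies use n = 20,000 cohorts for recovery, parsimony and
calibration checks (large enough that category cells are in the thousands),
n = 10,000 for binning shares, n = 2,000–5,000 for the AUC-equality and
rounding-degradation oracles over many replicates, and 20 seeded
replicates for the ranking-separation study. A single user seed fans out
to per-stage seeds by fixed offsets, so the split, the forest and the
bootstrap are individually reproducible and a full rerun with the same
seed writes a byte-identical score-table JSON (tested).

## Known limitations

* Main-effects, category-constant model: no interactions, and risk is
  flat within a band by construction.
* The smallest-positive-coefficient normalisation can inflate the point
  scale (see above); inspect the table and apply a ceiling when deploying.
* Automatic `m` selection is only as good as the validation AUC's noise
  level; prefer manual selection from the plotted curve for small cohorts.
* Binned calibration describes ordering, not absolute calibration; a
  formal calibration test is out of scope, though the binned table is
  exported for external tooling.
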