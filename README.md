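# pointscore

Automatic derivation of interpretable, integer point-based clinical risk
scores from tabular cohort data.

Clinical teams favour point-based scores — a handful of variables, each
category worth a small integer, summed to a total that stratifies risk at
the bedside without a computer. Building one by hand (choosing variables,
cutting continuous measurements into bands, weighting the bands, validating
the result) is slow and subjective. `pointscore` automates the whole
derivation from an episode-level table (e.g. first-day ICU vitals, labs and
demographics) with a binary outcome such as inpatient mortality, while
keeping every intermediate artifact open to clinical fine-tuning. It is
aimed at biostatisticians and clinical-informatics researchers working with
EHR-derived cohort tables.

## Method

Given predictors `X_1..X_p` and binary outcome `Y`, the derivation runs in
six stages:

1. **Ranking.** A random forest (100 trees, `mtry = floor(sqrt(p))`, trees
   grown to maximal depth on bootstrap samples) ranks variables by mean
   decrease in Gini impurity: for binary classification the node impurity
   is `Gini = 1 - p_0^2 - p_1^2`, and a variable's importance is the sum of
   `w(tau) * dGini(tau)` over nodes `tau` that split on it, averaged over
   trees, with `w(tau)` the fraction of samples reaching the node.
2. **Transformation.** Each continuous variable is cut at its training
   percentiles `k1, k2, k3, k4` (defaults 5, 20, 80, 95) into at most
   `K = 5` left-closed bands (`"a-b"` means `a <= x < b`); categorical
   variables with more than `K` levels have their rarest levels pooled into
   `Other`.
3. **Weighting.** Multivariable logistic regression on the category
   indicators; each variable is then re-referenced at its lowest-coefficient
   category and the model refitted so all coefficients are nonnegative.
   Coefficients are normalised by the smallest positive coefficient,
   `beta_new = beta / beta_lowest`, and rounded half away from zero to
   integer points, `beta_score = round(beta_new)`. An optional ceiling
   rescales the table to a fixed maximum total.
4. **Selection.** A parsimony curve (validation AUC of the integer score
   versus the number of top-ranked variables `m`) locates the plateau; `m`
   is chosen automatically (smallest `m` no larger model improves on by
   `delta = 0.005`) or manually.
5. **Fine-tuning.** The derived cutoffs are plain data (JSON-serialisable);
   domain experts can replace them with clinically round values and re-run
   stages 2–3.
6. **Evaluation.** On a held-out test set: AUC with a bootstrap 95% CI,
   sensitivity / specificity / PPV / NPV at the ROC upper-left-corner
   optimal threshold and at thresholds reaching about 95% sensitivity or
   specificity, plus observed event rates by score interval (binned
   calibration).

The split is 70% train / 10% validation / 20% test; implausible values are
set to missing and imputed with training medians (missing categorical cells
become an explicit `Unknown` category). The test partition is touched only
in stage 6.

The package also ships a synthetic EHR cohort generator
(`default_ehr_spec()`, `generate_cohort()`) whose outcome is drawn from a
known category-level integer score through a logistic link, so the full
pipeline can be validated against ground truth (parameter recovery, ranking
separation, calibration) without any restricted-access data.

## Worked example

```r
library(pointscore)

g <- generate_cohort(default_ehr_spec(n = 20000, seed = 42))
dat <- g$cohort$data
names(dat)[names(dat) == "..outcome.."] <- "death"

fit <- pointscore(death ~ ., data = dat, seed = 42, boot = 500,
                  score_ceiling = 100)
fit
```

```
Point-based risk score for 'death' (m = 9 of 21 candidates; seed 42)
Partitions: train 14000 / validation 2000 / test 4000

Point-based risk score
(normalised to ceiling 100 )

spo2
  <94.16327        15
  94.16327-95.69911   15
  95.69911-98.89857    7
  98.89857-100.3831    1
  >=100.3831        0

lactate
  <1.007137         0
  1.007137-1.345188    1
  1.345188-2.399197    7
  2.399197-3.158374   13
  >=3.158374       15

[... seven further variables ...]

Total score range: 0 to 99

Test AUC 0.835 (95% CI 0.814-0.859)
```

The parsimony curve selected `m = 9` of 21 candidates — exactly the nine
variables that carry signal in the generator — and the held-out AUC of the
integer score is 0.835. Scoring a new episode:

```r
ep <- data.frame(age = 81, heart_rate = 104, resp_rate = 22, sbp = 100,
                 temperature = 36.2, spo2 = 95.1, platelet = 180, bun = 34,
                 lactate = 2.8, sex = "Male", insurance = "Medicare")
predict(fit, ep, type = "score")     # 85
predict(fit, ep, type = "response")  # 0.936
```

An 85-point episode (elderly, tachycardic, tachypnoeic, hypotensive,
hypothermic, desaturating, uraemic, raised lactate) maps to a predicted
event risk of 0.94. `summary(fit)` prints the full threshold and
calibration tables, `plot(fit, "parsimony")` the selection curve, and
`write_pointscore_artifacts(fit, dir)` persists every artifact (ranking,
parsimony curve, transform spec, score table, evaluation report); the
score-table JSON embeds its transform spec and is the complete deployable
object (`read_score_table()`, `score_episodes()`).

To encode an existing published table instead of deriving one, see
`as_score_table()`; a published nine-variable ICU inpatient-mortality table
is included at `inst/extdata/icu_mortality_score.csv` as a reference
fixture.

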