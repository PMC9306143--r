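---
title: "Six strategies for risk prediction with systematically missing predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six strategies for risk prediction with systematically missing predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-centre clinical consortia pool biopsy data to build risk calculators,
but the centres rarely collect the same predictors. Some factors (here:
serum PSA and age) are measured for everyone; others — prostate volume,
digital rectal exam, family histories, medication use, ancestry — are
collected by some cohorts and not at all by others, with additional
patient-level gaps inside the cohorts that do collect them. The same
problem reappears at deployment: the end-user of a risk calculator knows
some subset of the predictors and should still get the best prediction
that subset supports.

`patternrisk` implements a pooled logistic-regression framework for this
setting. The outcome is clinically significant prostate cancer (biopsy
Gleason grade group ≥ 2); the predictor set is a schema of 12 factors,
2 mandatory (PSA, modeled per doubling on the log2 scale; age, per year)
and 10 optional. A *missingness pattern* `X*` is the subset of factors
observed for a query patient; every strategy in the package maps a
training multi-cohort dataset plus a pattern to a prediction engine
tailored to that pattern.

## The six strategies

All strategies produce logistic-regression risks `plogis(x'β)`; they
differ in which training rows and which encodings they use.

* **Available cases** — pool, across all cohorts, the records complete on
  `X*` and fit a main-effects model on `X*`. One fit per pattern (the
  "2^k submodels" idea).
* **Iterative BIC selection** — same pooling, plus bidirectional stepwise
  search by BIC allowing two-way interactions. If the selected model drops
  a factor entirely, the search restarts on the reduced factor set, whose
  complete-case pool is weakly larger; the loop runs to a fixed point
  (capped at 12 rounds). BIC here is `-2 logLik + p log n` with `p`
  counting all estimated coefficients including the intercept; the
  intercept convention only shifts every BIC by the same constant within
  one comparison, so selection is unaffected.
* **Cohort ensemble** — per cohort, fit on the intersection of `X*` with
  the factors that cohort measures in at least 40% of participants, using
  the cohort's complete cases; the reported risk is the unweighted mean of
  the per-cohort risks. Cohorts failing the minimum-size or separation
  guards are skipped with a warning; small cohorts are deliberately kept.
* **Categorization** — use *every* training record: continuous optional
  factors are stratified (prostate volume to < 30, 30–50, > 50 cc, the
  boundaries belonging to the middle stratum) and "missing" is added as an
  explicit level to each optional factor. One model serves all patterns;
  at prediction, factors the user does not supply sit at their missing
  level.
* **Missing indicator** — like categorization but continuous factors keep
  their value: volume enters as a missing indicator plus a zero-filled
  `log2(volume)` term. Since volume is the only sometimes-missing
  continuous factor, this differs from categorization in exactly the
  volume terms.
* **Imputation** — multiple imputation by chained equations on the pooled
  training set (30 imputations, 10 cycles each; both configurable), a full
  12-factor fit on each completed dataset, and coefficient averaging
  (Rubin's point estimate, with Rubin's total variance retained). At
  prediction time, factors the user lacks are filled with training-set
  marginals: the mean of observed `log2` values for continuous factors and
  the most frequent level for binary ones (a "mean" is only defined for
  continuous factors; the modal level is the analogue we chose).

Two encoding decisions deserve note. First, second-degree prostate-cancer
and first-degree breast-cancer family history are collected jointly or not
at all at the cohort level, so giving each its own missing level would be
collinear; under the all-data codings they are combined into one 5-level
factor (none / second-degree-PCa only / first-degree-BCa only / both /
missing). We apply the combination **only when the pair actually has
missing values in the training data**: with fully complete data the
combination would silently add an interaction term ("both" as a free
level) and the all-data codings would no longer reduce to the plain
main-effects model, breaking the complete-data equivalence that anchors
the test suite. Second, when a query omits a factor that was complete in
training (so no missing level exists), prediction falls back to the
factor's reference level with a warning rather than refusing to answer.

## Validation machinery

* **CIL** (calibration-in-the-large): `100 · (mean predicted risk −
  observed event rate)`; negative values mean under-prediction. The CI is
  a normal approximation on per-patient differences (no method is
  canonical here; this is an implementation decision).
* **AUC**: Mann–Whitney concordance with ties counted ½, reported as a
  percentage, with a DeLong placement-value CI (again our choice of CI
  method; a seeded bootstrap is easy to add via resampling if wanted).
* **Calibration curves**: records stably sorted by predicted risk, split
  into near-equal decile bins (remainder to the leading bins — tie
  handling is unspecified in the literature we follow, so the stable sort
  is pinned by tests), each bin reporting mean predicted risk, observed
  proportion and a Wilson 95% interval.
* **External validation** derives each test patient's pattern, fetches the
  tailored model (cached per pattern inside a `strategy_engine`), and
  predicts; patients whose pattern cannot be served are listed in the
  report, never silently dropped.
* **Leave-one-cohort-out CV** holds out each cohort in turn and summarizes
  CIL and AUC by median and IQR across folds.

An exact property anchors calibration: any maximum-likelihood logistic fit
with an intercept satisfies the score equation, so its mean fitted
probability equals the observed event rate and its training-data CIL is
0 to numerical precision. The tests assert `|CIL| < 1e-6`.

## The synthetic multi-cohort generator

The real consortium data are not redistributable, so the package carries a
generator that reproduces the *statistical structure* the methods care
about, and every empirical claim in the package is made on it:

* **True model.** Outcomes are Bernoulli with log-odds linear in the raw
  encoding; the default coefficients are the natural logs of the published
  full-model odds ratios (PSA per doubling 2.38, volume per doubling 0.25,
  abnormal DRE 1.95, prior negative biopsy 0.32, age per year 1.07, …).
  The intercept is solved by monotone 1-D root finding so the expected
  pooled training prevalence is 0.28.
* **Covariates.** PSA and prostate volume are log-normal, age normal
  (clipped to 30–95 years), joined by a Gaussian copula with modest
  positive correlation (PSA–volume 0.3, PSA–age 0.2, age–volume 0.15);
  the nine binary factors are independent Bernoulli with clinic-plausible
  prevalences (abnormal DRE 25%, prior negative biopsy 25%, 5-ARI use
  10%, prior PSA screen 65%, African ancestry 12%, Hispanic ethnicity 8%,
  first-degree PCa family history 15%, the extended family histories 10%
  each). None of these laws is a claim about any real cohort; they are
  module parameters chosen once for realism.
* **Default scenario.** Ten training cohorts of sizes 3,000 down to 250
  (12,650 records), with per-cohort shifts in PSA and age producing
  heterogeneous prevalences around the 0.28 pooled target; cohort-level
  systematic non-collection (e.g. some cohorts never record volume, some
  never the extended family-history pair — which is always erased jointly
  so the pair stays jointly observed or jointly missing); and sporadic
  patient-level missingness of 20–40% per cohort. One held-out validation
  cohort (n = 2,000) has *shifted covariates* (higher PSA, older) chosen
  so its expected prevalence is ≈ 0.32 under the *same* outcome model,
  plus light 5% sporadic missingness, as befits a single high-volume
  centre's retrospective series. Shifting covariates rather than the
  intercept is deliberate: it gives the validation cohort a genuinely
  different case mix while keeping a correctly specified pooled model
  transportable, so external CIL should be near 0 and we can test that it
  is. An intercept-shifted validation cohort would instead build a fixed
  calibration error into the scenario and the test would measure the
  scenario, not the code.
* **Missingness mechanisms.** MCAR by default (independent erasure at the
  sporadic rate); optionally MAR with erasure probability logistic in the
  always-observed `log2(PSA)` and age, the per-factor intercept solved so
  the marginal rate still matches — MAR holds by construction, giving the
  imputation-based methods a fair test.
* The pre-erasure table of every cohort is kept as an attribute, so tests
  can compare imputations and predictions against the erased truth.

What the generator does *not* emulate: correlations between the binary
factors and the continuous ones, informative (MNAR) missingness,
within-cohort effect heterogeneity, or repeat biopsies per patient. Tests
passing on this generator therefore certify the machinery — encodings,
pooling, selection, imputation, metrics — under the stated mechanisms,
not performance on real clinic data.

## Numerical choices

* Logistic fits use IRLS with relative-deviance tolerance `1e-12`;
  covariance is the inverse observed information. Degenerate outcomes,
  samples below the minimum size (n ≥ 25, events ≥ 5, non-events ≥ 5 —
  set low on purpose, small centres are kept) and perfect separation
  raise classed errors so each strategy can apply its own policy (the
  ensemble skips and logs; everything else propagates). An optional ridge
  term on the information matrix (`logistic_control(ridge =)`) is
  available for degenerate inputs; it is never used by default.
* Predicted risks are clipped to `(1e-12, 1 − 1e-12)`.
* Stepwise moves are enumerated and tie-broken in term-name order;
  dropping a main effect removes its interactions in the same move, and an
  interaction is only eligible while both parents are in the model. The
  mandatory factors are forced into every candidate model — they are by
  definition always available, and forcing them keeps the restart loop's
  factor-set shrinkage meaningful. The search starts from the full
  main-effects model, matching the refinement-of-`X*` reading of the
  procedure.
* MICE conditionals are Bayesian linear regression on the log2 scale for
  continuous factors and logistic regression with a normal posterior draw
  for binary ones; a factor whose conditional cannot be fit (degenerate or
  separated) falls back to a marginal draw for that cycle. All chains are
  driven by one seed.
* Library serialization stores coefficients both in decimal and as C99
  hex floats; the hex copy is authoritative on load, so a round-tripped
  library predicts bit-identically, and a digest over the hex payload
  catches corruption.

## Problem sizes used by the tests and the acceptance script

Parameter recovery is checked on complete data of n = 50,000 (each
coefficient within 3 estimated SEs at a fixed seed; pooled 95% Wald
coverage across 20 seeds × 13 coefficients required to land in
[0.90, 0.99] — per-coefficient coverage over 20 replicates is a multiple
of 0.05, so pooling is the resolution-respecting reading of that check).
External validation and the strategy-concordance check run on the default
scenario (12,650 training records, 2,000 validation patients); the
deployment library is built over all 2^10 = 1,024 patterns. These sizes
are a deliberate miniature — about one quarter — of the motivating
consortium, chosen to keep a full end-to-end run on one core in minutes
while leaving every sample-size guard and pattern-diversity effect
active.

## Known limitations

* Categorical factors with more than two raw levels are supported by the
  encoders, but the stepwise search treats each dummy column as its own
  term (no group add/drop), and the generator only draws binary optional
  factors.
* The iterative-BIC restart re-runs the full stepwise search each round;
  whether the original procedure re-selected interactions from scratch is
  unknowable from its description, and this is the cleaner choice.
* MICE's multinomial conditional (for future multi-level factors) is not
  implemented; binary and continuous cover the default schema.
* The cohort ensemble weights cohorts equally, not by size — faithful to
  the description it implements, though size weighting would be a natural
  variant.
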