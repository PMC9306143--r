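# patternrisk

Clinical risk prediction from multiple heterogeneous cohorts with
**systematically missing predictors** — some centres never collect some
risk factors at all, patients miss others sporadically, and the end-user
of the deployed calculator supplies whatever subset they have.

The package targets prediction of clinically significant prostate cancer
(biopsy Gleason grade group ≥ 2) from a 12-factor schema: PSA (ng/mL, per
doubling) and age (years) are mandatory; digital rectal exam, prostate
volume (cc, per doubling), prior negative biopsy, 5-ARI use, prior PSA
screen, African ancestry, Hispanic ethnicity, and first-degree prostate-,
second-degree prostate- and first-degree breast-cancer family history are
optional. All models are logistic regressions

&nbsp;&nbsp;&nbsp;&nbsp;Pr(Y = 1 | X\*) = expit(β₀ + β′X\*),

where X\* is the subset of predictors observed for the query patient.

Six missing-data accommodation strategies share one fit/predict contract:

| strategy | training rows | idea |
|---|---|---|
| `available_cases` | complete on X\* | pool across cohorts, main effects on X\* (the "2^k submodels" method) |
| `iterative_bic` | complete on X\* | stepwise BIC with two-way interactions; restarts on the larger pool whenever a factor is dropped |
| `cohort_ensemble` | per cohort | per-cohort fits on factors the cohort measures in ≥ 40% of participants; risks averaged |
| `categorization` | all | continuous factors stratified, "missing" an explicit level |
| `missing_indicator` | all | like categorization, but volume keeps its value plus a missing indicator |
| `imputation` | all | MICE (30 imputations × 10 cycles), coefficient-averaged fit; marginal fill at prediction |

Validation follows the field's standard battery: calibration-in-the-large
(CIL = 100·(mean predicted risk − event rate), negative = under-prediction),
AUC with DeLong 95% CI, decile calibration curves with Wilson intervals,
external validation on a held-out cohort, and leave-one-cohort-out
cross-validation. For deployment, `build_pattern_library()` pre-fits all
2^10 = 1,024 per-pattern submodels, serializes them to JSON, and
`predict_risk()` answers queries with transparency metadata (sample size,
contributing cohorts, odds ratios behind the answer).

Because the motivating consortium data are not redistributable, the
package ships a synthetic multi-cohort generator whose default true model
uses the published full-model odds ratios (PSA 2.38 per doubling, volume
0.25 per doubling, abnormal DRE 1.95, prior negative biopsy 0.32, …) and
whose default scenario mirrors the consortium in miniature: 10 training
cohorts (250–3,000 records, pooled prevalence ≈ 0.28) with cohort-level
non-collection plus 20–40% sporadic missingness, and one covariate-shifted
validation cohort (n = 2,000, prevalence ≈ 0.32). See the methods
vignette (`vignettes/missing-data-strategies.Rmd`) for every modeling and
numerical decision.

## Worked example

```r
library(patternrisk)

sc <- default_scenario(seed = 1)
sc$training
#> multi_cohort: 10 cohorts, 12650 records total
#> cohort_data 'cohort_01': 3000 records, 947 events (prevalence 0.316)
#> cohort_data 'cohort_02': 2400 records, 691 events (prevalence 0.288)
#> ...
#> cohort_data 'cohort_10': 250 records, 53 events (prevalence 0.212)

# external validation of the deployed strategy on the held-out cohort
rep <- external_validate("available_cases", sc$training, sc$validation)
rep
#> validation_report [available_cases] on 'validation' (n=2000, prevalence 0.343)
#>   CIL   0.3% (95% CI  -1.5,   2.1)
#>   AUC  79.4% (95% CI  77.3,  81.4)
```

CIL ≈ 0 says the pooled model transports to the covariate-shifted
validation cohort without systematic over- or under-prediction; the AUC
matches the generating model's own discrimination on that population
(≈ 79.5%), i.e. the strategy loses essentially nothing to the missing
data under this scenario.

```r
# deployment: pre-fit all 1,024 pattern submodels and answer a query
lib <- build_pattern_library(sc$training)
predict_risk(lib, list(psa = 6.5, age = 66, dre = "abnormal", volume = 40))
#> Risk of clinically significant prostate cancer: 36.51%
#>   strategy available_cases; pattern {psa,age,dre,volume}
#>   model behind the answer: n=5174 from 7 cohort(s)
#>   terms (odds ratios):
#>          term coefficient odds_ratio
#>   (Intercept)      0.0517      1.053
#>      psa_log2      0.8746      2.398
#>           age      0.0496      1.051
#>  dre_abnormal      0.6470      1.910
#>   volume_log2     -1.2941      0.274
```

The answer is served by the submodel for exactly the supplied pattern,
fitted to the 5,174 pooled records complete on those four factors; the
fitted odds ratios sit close to the generator's truth (PSA 2.38, DRE
1.95, volume 0.25 per doubling).

A thin command-line front end wraps the same functions
(`inst/cli/patternrisk.R`): subcommands `generate`, `fit`, `validate`
(external or `--loco`), `predict` (`--psa 6.5 --age 66 --dre abnormal ...`)
and `inspect`.

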