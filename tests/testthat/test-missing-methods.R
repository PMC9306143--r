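test_that("volume stratification follows the published cutpoints", {
  expect_identical(categorize_volume(25), "lt30")
  expect_identical(categorize_volume(30), "30to50")   # closed interval
  expect_identical(categorize_volume(50), "30to50")
  expect_identical(categorize_volume(51), "gt50")
  expect_identical(categorize_volume(NA), "missing")
  expect_identical(categorize_volume(c(10, 45, 80, NA)),
                   c("lt30", "30to50", "gt50", "missing"))
  expect_error(categorize_volume(0), "> 0")
})

test_that("the family-history pair combines into a 5-level factor", {
  expect_identical(combine_family_history("yes", "no"), "pca2_only")
  expect_identical(combine_family_history("no", "yes"), "bca1_only")
  expect_identical(combine_family_history("yes", "yes"), "both")
  expect_identical(combine_family_history("no", "no"), "none")
  expect_identical(combine_family_history(NA, NA), "missing")
  expect_error(combine_family_history("yes", NA), "consistency error")
})

test_that("available cases pools exactly the pattern-complete records", {
  mc <- tiny_multicohort(c(300, 250), miss = list(volume = 0.3, dre = 0.2))
  n_total <- sum(vapply(mc, nrow, integer(1)))
  pm <- available_cases_fit(mc, c("psa", "age"))
  expect_equal(pm$n_obs, n_total)  # mandatory-only uses every record
  expect_equal(pm$n_cohorts, 2L)

  pm_vol <- available_cases_fit(mc, c("psa", "age", "volume"))
  expect_equal(pm_vol$n_obs, sum(!is.na(pool_records(mc)$volume)))
  expect_identical(pm_vol$effective_pattern, c("psa", "age", "volume"))

  # a factor collected nowhere -> insufficient data, pattern named
  dfs <- lapply(mc, function(cd) { d <- as.data.frame(cd); d$volume <- NA; d })
  mc0 <- multi_cohort(lapply(dfs, cohort_data, schema = tiny_schema()))
  expect_error(available_cases_fit(mc0, c("psa", "age", "volume")),
               class = "patternrisk_insufficient_data")
})

test_that("available cases recovers the generating coefficients", {
  beta <- c(int = -1.2, psa_log2 = 0.9, age = 0.04, dre_abnormal = 0.7,
            volume_log2 = -1.0, prior_neg_biopsy_yes = -0.9)
  mc <- tiny_multicohort(c(4000, 4000), miss = list(volume = 0.2))
  pm <- available_cases_fit(mc, schema_factor_names(tiny_schema()))
  m <- pm$payload$model
  se <- sqrt(diag(m$vcov))
  truth <- c(`(Intercept)` = beta[["int"]] - beta[["age"]] * 64 +
               beta[["volume_log2"]] * -log2(40),
             psa_log2 = beta[["psa_log2"]], age = beta[["age"]],
             dre_abnormal = beta[["dre_abnormal"]],
             volume_log2 = beta[["volume_log2"]],
             prior_neg_biopsy_yes = beta[["prior_neg_biopsy_yes"]])
  expect_true(all(abs(m$coefficients - truth[m$terms]) < 3 * se))
})

test_that("iterative BIC drops a sparsely collected noise factor and regrows the pool", {
  # dre is collected only in the small first cohort and carries no signal
  set.seed(500)
  mk <- function(n, seed, cid, dre_everywhere) {
    df <- tiny_records(n, seed,
                       beta = c(int = -1, psa_log2 = 0.9, age = 0.04,
                                dre_abnormal = 0, volume_log2 = -1,
                                prior_neg_biopsy_yes = -0.9))
    if (!dre_everywhere) df$dre <- NA
    df$cohort_id <- cid
    cohort_data(df, tiny_schema(), cohort_id = cid)
  }
  mc <- multi_cohort(list(mk(400, 1, "small", TRUE),
                          mk(1500, 2, "big1", FALSE),
                          mk(1500, 3, "big2", FALSE)))
  full <- schema_factor_names(tiny_schema())
  n_first_pool <- nrow(complete_case_subset(mc, full))
  expect_equal(n_first_pool, 400L)
  pm <- iterative_bic_fit(mc, full)
  expect_false("dre" %in% pm$effective_pattern)
  expect_gt(pm$n_obs, n_first_pool)  # the refit pool strictly grew
  # effective pattern is a subset of the query and contains the mandatory
  expect_true(all(c("psa", "age") %in% pm$effective_pattern))
  expect_true(all(pm$effective_pattern %in% full))
})

test_that("iterative BIC at a fixed point reuses the available-cases pool", {
  mc <- tiny_multicohort(c(2000, 1500))
  pat <- c("psa", "age", "volume")
  pm <- iterative_bic_fit(mc, pat)
  ac <- available_cases_fit(mc, pat)
  expect_equal(pm$n_obs, ac$n_obs)  # same pooled data when nothing dropped
})

test_that("cohort ensemble respects the 40% availability rule and averages", {
  # volume measured in 39% of cohort a -> excluded there
  df_a <- tiny_records(200, seed = 41)
  df_a$volume[79:200] <- NA  # 78/200 = 39% measured
  df_a$cohort_id <- "a"
  df_b <- tiny_records(300, seed = 42)
  df_b$cohort_id <- "b"
  mc <- multi_cohort(list(cohort_data(df_a, tiny_schema()),
                          cohort_data(df_b, tiny_schema())))
  pm <- cohort_ensemble_fit(mc, c("psa", "age", "volume"))
  pats <- lapply(pm$payload$members, `[[`, "pattern")
  names(pats) <- vapply(pm$payload$members, `[[`, character(1), "cohort_id")
  expect_false("volume" %in% pats[["a"]])
  expect_true("volume" %in% pats[["b"]])

  # prediction is the unweighted mean of the member risks
  q <- list(psa = 6, age = 66, volume = 38)
  risks <- vapply(pm$payload$members, function(mb) {
    row <- patternrisk:::values_to_row(q, mb$pattern, tiny_schema())
    enc <- patternrisk:::encode_raw(row, mb$pattern, tiny_schema())
    predict_proba(mb$model, enc$x)
  }, numeric(1))
  expect_equal(predict_for_patient(pm, q), mean(risks), tolerance = 1e-12)

  # single-cohort training: ensemble equals that cohort's model
  one <- multi_cohort(list(cohort_data(df_b, tiny_schema())))
  pm1 <- cohort_ensemble_fit(one, c("psa", "age", "volume"))
  ac1 <- available_cases_fit(one, c("psa", "age", "volume"))
  expect_equal(predict_for_patient(pm1, q), predict_for_patient(ac1, q),
               tolerance = 1e-12)
})

test_that("categorization uses every record and serves any sub-pattern", {
  mc <- tiny_multicohort(c(300, 250), miss = list(volume = 0.3, dre = 0.2))
  n_total <- sum(vapply(mc, nrow, integer(1)))
  pm <- categorization_fit(mc)
  expect_equal(pm$n_obs, n_total)
  # user supplies only the mandatory factors: all optional at missing level
  # (a factor that was complete in training warns and falls back to its
  # reference level)
  expect_warning(r <- predict_for_patient(pm, list(psa = 5, age = 62)),
                 "prior_neg_biopsy")
  expect_true(r > 0 && r < 1)
  # a richer query moves the prediction
  r2 <- suppressWarnings(
    predict_for_patient(pm, list(psa = 5, age = 62, volume = 80)))
  expect_false(isTRUE(all.equal(r, r2)))
})

test_that("missing-indicator volume block behaves as specified", {
  mc <- tiny_multicohort(c(400, 300), miss = list(volume = 0.3))
  pm <- suppressWarnings(missing_indicator_fit(mc))
  terms <- pm$payload$model$terms
  expect_true(all(c("volume_missing_ind", "volume_log2_obs") %in% terms))

  # for a patient with volume missing, the volume block contributes only
  # the indicator coefficient
  sch <- tiny_schema()
  row <- patternrisk:::values_to_row(list(psa = 5, age = 60, dre = "normal",
                                          prior_neg_biopsy = "no"),
                                     schema_factor_names(sch), sch)
  e <- patternrisk:::encode_with_recode(row, pm$payload$recode_info, sch)
  expect_equal(unname(e$x[1, "volume_missing_ind"]), 1)
  expect_equal(unname(e$x[1, "volume_log2_obs"]), 0)

  # compared with categorization on the same data, only the volume terms
  # differ
  pmc <- categorization_fit(mc)
  t_mi <- setdiff(pm$payload$model$terms, pmc$payload$model$terms)
  t_cat <- setdiff(pmc$payload$model$terms, pm$payload$model$terms)
  expect_true(all(grepl("^volume", c(t_mi, t_cat))))
})

test_that("a never-missing continuous factor drops its indicator with a warning", {
  mc <- tiny_multicohort(c(300, 250), miss = list(dre = 0.2))
  expect_warning(pm <- missing_indicator_fit(mc), "indicator dropped")
  expect_false("volume_missing_ind" %in% pm$payload$model$terms)
  expect_true("volume_log2_obs" %in% pm$payload$model$terms)
})

test_that("MICE is deterministic, honest on complete data, and unbiased under MCAR", {
  sch <- tiny_schema()
  # complete data: all m outputs identical to the input
  comp <- tiny_records(120, seed = 61)
  comp$cohort_id <- "c"
  out <- mice_impute(comp, sch, m = 4, cycles = 2, seed = 7)
  expect_length(out, 4L)
  for (d in out) expect_identical(d, comp)

  # same seed twice -> identical imputations
  df <- tiny_records(600, seed = 62)
  df$volume[runif(600) < 0.3] <- NA
  df$dre[runif(600) < 0.2] <- NA
  a <- mice_impute(df, sch, m = 3, cycles = 3, seed = 11)
  b <- mice_impute(df, sch, m = 3, cycles = 3, seed = 11)
  expect_identical(a, b)
  # ... and no imputed cell is left missing
  expect_false(anyNA(a[[2]]))

  # factor with zero observed values cannot be imputed
  df0 <- df; df0$volume <- NA
  expect_error(mice_impute(df0, sch, m = 2, cycles = 2, seed = 1),
               class = "patternrisk_cannot_impute")

  # MCAR-erased continuous factor: pooled imputed-cell mean matches the
  # pre-erasure truth within Monte-Carlo error
  cfg <- synthetic_config(list(cohort_spec("c1", 4000,
                                           sporadic_rate = 0.3)),
                          seed = 23L)
  mcd <- generate_multicohort(cfg)[[1]]
  complete <- attr(mcd, "complete")
  imp <- mice_impute(as.data.frame(mcd), default_schema(), m = 5,
                     cycles = 5, seed = 29)
  mis <- is.na(mcd$volume)
  imp_mean <- mean(vapply(imp, function(d) mean(log2(d$volume[mis])),
                          numeric(1)))
  true_mean <- mean(log2(complete$volume[mis]))
  se <- sd(log2(complete$volume)) / sqrt(sum(mis))
  expect_lt(abs(imp_mean - true_mean), 3 * se)
})

test_that("imputation strategy collapses to available cases on complete data", {
  mc <- tiny_multicohort(c(700, 500))
  full <- schema_factor_names(tiny_schema())
  pmi <- imputation_fit(mc, control = engine_control(m = 30))
  expect_equal(pmi$payload$m, 30L)  # 30 imputations by default
  ac <- available_cases_fit(mc, full)
  expect_equal(pmi$payload$model$coefficients,
               ac$payload$model$coefficients, tolerance = 1e-10)

  # prediction-time marginal fill: volume filled with the training mean of
  # log2(volume) observed values
  mc2 <- tiny_multicohort(c(500, 400), miss = list(volume = 0.3))
  pm2 <- imputation_fit(mc2, control = engine_control(m = 3, cycles = 3))
  v <- pool_records(mc2)$volume
  expect_equal(log2(pm2$payload$marginals$volume),
               mean(log2(v[!is.na(v)])), tolerance = 1e-12)
  r_miss <- predict_for_patient(pm2, list(psa = 6, age = 64))
  r_fill <- predict_for_patient(pm2, list(
    psa = 6, age = 64, volume = pm2$payload$marginals$volume,
    dre = pm2$payload$marginals$dre,
    prior_neg_biopsy = pm2$payload$marginals$prior_neg_biopsy))
  expect_equal(r_miss, r_fill, tolerance = 1e-12)
})

test_that("missing indicator equals available cases on complete data", {
  mc <- tiny_multicohort(c(600, 400))
  full <- schema_factor_names(tiny_schema())
  ac <- available_cases_fit(mc, full)
  mi <- suppressWarnings(missing_indicator_fit(mc))
  set.seed(83)
  for (i in 1:20) {
    q <- list(psa = exp(log(6) + 0.5 * rnorm(1)), age = runif(1, 45, 85),
              dre = sample(c("normal", "abnormal"), 1),
              volume = exp(log(40) + 0.4 * rnorm(1)),
              prior_neg_biopsy = sample(c("no", "yes"), 1))
    expect_equal(predict_for_patient(mi, q), predict_for_patient(ac, q),
                 tolerance = 1e-10)
  }
})

test_that("all six strategies honor the shared fit/predict contract", {
  mc <- tiny_multicohort(c(500, 400), miss = list(volume = 0.25, dre = 0.15))
  sch <- tiny_schema()
  patterns <- list(c("psa", "age"),
                   c("psa", "age", "volume"),
                   c("psa", "age", "dre", "prior_neg_biopsy"),
                   schema_factor_names(sch))
  q <- list(psa = 7, age = 68, dre = "abnormal", volume = 33,
            prior_neg_biopsy = "no")
  ctl <- engine_control(m = 3, cycles = 3, seed = 5)
  for (s in STRATEGIES) {
    eng <- strategy_engine(s, mc, ctl)
    eng2 <- strategy_engine(s, mc, ctl)
    for (pat in patterns) {
      pm <- suppressWarnings(get_pattern_model(eng, pat))
      r <- suppressWarnings(predict_for_patient(pm, q[pat[pat %in% names(q)]]))
      expect_true(r > 0 && r < 1)
      pm2 <- suppressWarnings(get_pattern_model(eng2, pat))
      r2 <- suppressWarnings(predict_for_patient(pm2, q[pat[pat %in% names(q)]]))
      expect_identical(r, r2)  # deterministic under a fixed seed
    }
  }
})

test_that("query validation names the offending input", {
  mc <- tiny_multicohort(c(300, 250))
  pm <- available_cases_fit(mc, c("psa", "age", "volume"))
  expect_error(predict_for_patient(pm, list(psa = 5, age = 60)),
               class = "patternrisk_contract")
  expect_error(predict_for_patient(pm, list(psa = -2, age = 60,
                                            volume = 30)), "psa")
  expect_error(predict_for_patient(pm, list(psa = 5, age = 140,
                                            volume = 30)), "age")
  expect_error(predict_for_patient(pm, list(psa = 5, age = 60, volume = 30,
                                            shoe_size = 44)), "unknown")
})
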