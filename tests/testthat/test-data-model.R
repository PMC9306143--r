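test_that("CSV write/read round-trips values and missingness cell-for-cell", {
  cd <- tiny_cohort(60, seed = 3, miss = list(volume = 0.3, dre = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cd, path)
  back <- read_cohort_csv(path, tiny_schema())
  for (nm in c("psa", "age", "volume")) {
    expect_equal(back[[nm]], cd[[nm]], tolerance = 1e-12)
    expect_identical(is.na(back[[nm]]), is.na(cd[[nm]]))
  }
  expect_identical(back$dre, cd$dre)
  expect_identical(back$outcome, cd$outcome)

  # the "NA" sentinel dialect round-trips too
  write_cohort_csv(cd, path, na = "NA")
  back2 <- read_cohort_csv(path, tiny_schema())
  expect_identical(is.na(back2$volume), is.na(cd$volume))
})

test_that("rows violating record invariants are rejected with diagnostics", {
  txt <- paste(
    "cohort_id,outcome,psa,age,dre,volume,prior_neg_biopsy",
    "a,1,4.0,65,normal,35,no",
    "a,0,,70,normal,40,no",        # missing mandatory PSA -> rejected
    "a,1,5.0,66,abnormal,,yes",    # missing optional volume -> kept
    "a,,6.0,60,normal,30,no",      # missing outcome -> rejected
    "a,0,3.0,150,normal,30,no",    # age out of range -> rejected
    sep = "\n")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, path)
  expect_warning(cd <- read_cohort_csv(path, tiny_schema()), "rejected 3")
  expect_equal(nrow(cd), 2L)
  expect_true(is.na(cd$volume[2]))
  rej <- attr(cd, "rejected")
  expect_setequal(rej$row, c(2L, 4L, 5L))
  expect_match(rej$reason[rej$row == 2], "psa")
  expect_match(rej$reason[rej$row == 4], "outcome")
  # same file under on_invalid = "error" stops instead
  expect_error(read_cohort_csv(path, tiny_schema(), on_invalid = "error"),
               "validation error")
})

test_that("structural CSV problems raise schema/parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cohort_id,outcome,psa,age,dre,volume",
               "a,1,4,65,normal,35"), path)
  expect_error(read_cohort_csv(path, tiny_schema()), "schema error")
  writeLines(c("cohort_id,outcome,psa,age,dre,volume,prior_neg_biopsy",
               "a,1,4,65,normal,35,no",
               "a,1,four,65,normal,35,no"), path)
  expect_error(read_cohort_csv(path, tiny_schema()),
               "parse error.*'psa', row 2")
})

test_that("missingness_summary computes per-cohort fractions, 0 for mandatory", {
  mc <- multi_cohort(list(
    tiny_cohort(4, seed = 1, cohort_id = "a", miss = list(dre = 0)),
    tiny_cohort(10, seed = 2, cohort_id = "b")))
  # force exact counts: 1 of 4 DRE missing in cohort a, all volume in b
  df_a <- as.data.frame(mc[["a"]]); df_a$dre[2] <- NA
  df_b <- as.data.frame(mc[["b"]]); df_b$volume <- NA
  mc <- multi_cohort(list(cohort_data(df_a, tiny_schema()),
                          cohort_data(df_b, tiny_schema())))
  ms <- missingness_summary(mc)
  get <- function(c, f) ms$frac_missing[ms$cohort_id == c & ms$factor == f]
  expect_equal(get("a", "dre"), 0.25)
  expect_equal(get("b", "volume"), 1.0)
  expect_equal(get("a", "psa"), 0)
  expect_equal(get("b", "age"), 0)
  expect_true(all(ms$frac_missing >= 0 & ms$frac_missing <= 1))
})

test_that("sporadic missingness rate is recovered at large n", {
  cfg <- synthetic_config(list(cohort_spec("c1", 5000, sporadic_rate = 0.2)),
                          seed = 11L)
  mc <- generate_multicohort(cfg)
  ms <- missingness_summary(mc)
  frac <- ms$frac_missing[ms$factor == "dre"]
  expect_lt(abs(frac - 0.2), 0.02)  # 3-SD binomial bound at n = 5000
})

test_that("complete_case_subset pools complete records in stable order", {
  mc <- tiny_multicohort(c(100, 80), miss = list(volume = 0.4))
  sch <- tiny_schema()
  all_rec <- complete_case_subset(mc, c("psa", "age"))
  expect_equal(nrow(all_rec), 180L)  # mandatory-only pattern returns all
  expect_equal(unique(all_rec$cohort_id), c("c1", "c2"))  # cohort order

  with_vol <- complete_case_subset(mc, c("psa", "age", "volume"))
  expect_equal(nrow(with_vol),
               sum(!is.na(pool_records(mc)$volume)))

  # monotone: adding a factor never increases the subset
  set.seed(7)
  opt <- schema_optional(sch)
  for (i in 1:10) {
    base <- sample(opt, 1)
    bigger <- union(base, sample(opt, 2))
    expect_gte(nrow(complete_case_subset(mc, base)),
               nrow(complete_case_subset(mc, bigger)))
  }

  # toy: 5 records, 2 missing volume -> 3 complete on volume
  df <- tiny_records(5, seed = 5)
  df$volume[c(2, 4)] <- NA
  df$cohort_id <- "t"
  toy <- multi_cohort(list(cohort_data(df, sch)))
  expect_equal(nrow(complete_case_subset(toy, c("psa", "age", "volume"))), 3L)
})

test_that("a factor no cohort collected yields an empty pooled subset", {
  mc <- tiny_multicohort(c(50, 50), miss = list(volume = 0))
  dfs <- lapply(mc, function(cd) { d <- as.data.frame(cd); d$volume <- NA; d })
  mc2 <- multi_cohort(lapply(dfs, cohort_data, schema = tiny_schema()))
  expect_equal(nrow(complete_case_subset(mc2, c("psa", "age", "volume"))), 0L)
})

test_that("raw design encoding transforms, dummy-codes and is deterministic", {
  sch <- tiny_schema()
  df <- data.frame(psa = 4, age = 65, dre = "abnormal", volume = 40,
                   prior_neg_biopsy = "no", stringsAsFactors = FALSE)
  enc <- encode_design(df, schema_factor_names(sch), sch, coding = "raw")
  expect_identical(enc$terms, c("(Intercept)", "psa_log2", "age",
                                "dre_abnormal", "volume_log2",
                                "prior_neg_biopsy_yes"))
  expect_equal(unname(enc$x[1, "psa_log2"]), 2)        # log2(4)
  expect_equal(unname(enc$x[1, "dre_abnormal"]), 1)
  expect_equal(unname(enc$x[1, "prior_neg_biopsy_yes"]), 0)

  # full 12-factor default-schema pattern: 12 predictor terms + intercept
  dsch <- default_schema()
  rec <- tiny_records(1, seed = 1)[, c("psa", "age")]
  rec <- cbind(rec, volume = 40, dre = "normal")
  for (nm in setdiff(schema_factor_names(dsch),
                     c("psa", "age", "volume", "dre")))
    rec[[nm]] <- "no"
  enc12 <- encode_design(rec, schema_factor_names(dsch), dsch, "raw")
  expect_length(enc12$terms, 13L)

  big <- tiny_records(200, seed = 8)
  e1 <- encode_design(big, schema_factor_names(sch), sch, "raw")
  e2 <- encode_design(big, schema_factor_names(sch), sch, "raw")
  expect_identical(e1, e2)  # byte-identical across runs

  expect_error(encode_design(transform(df, psa = -1),
                             schema_factor_names(sch), sch, "raw"),
               "log2")
  expect_error(encode_design(transform(df, dre = "odd"),
                             schema_factor_names(sch), sch, "raw"),
               "unknown level")
})

test_that("categorized coding activates the right volume stratum", {
  sch <- tiny_schema()
  train <- tiny_records(80, seed = 2)
  train$volume[1:10] <- NA
  enc <- encode_design(train, schema = sch, coding = "categorized")
  row <- train[0, ]
  row[1, ] <- train[11, ]
  row$volume <- 40
  e <- patternrisk:::encode_with_recode(row, enc$recode_info, sch)
  expect_equal(unname(e$x[1, "volume_cat_30to50"]), 1)
  expect_equal(unname(e$x[1, "volume_cat_gt50"]), 0)
  expect_equal(unname(e$x[1, "volume_cat_missing"]), 0)
})

test_that("pattern canonicalization enforces mandatory factors", {
  sch <- tiny_schema()
  expect_identical(as_pattern("volume", sch), c("psa", "age", "volume"))
  expect_error(as_pattern("nope", sch), "not in schema")
  expect_error(derive_pattern(list(psa = 4), sch), "mandatory")
  p <- derive_pattern(list(psa = 4, age = 60, volume = NA, dre = "normal"),
                      sch)
  expect_identical(p, c("psa", "age", "dre"))
  expect_identical(pattern_key(c("psa", "age")), "age+psa")
})
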