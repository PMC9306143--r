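#' Strategy names
#'
#' The six missing-data accommodation strategies sharing one fit/predict
#' contract: `available_cases` (pool records complete on the query pattern,
#' main-effects fit), `iterative_bic` (same pooling plus stepwise BIC
#' selection with two-way interactions and a restart loop that re-pools
#' whenever a factor is dropped), `cohort_ensemble` (per-cohort fits on the
#' factors a cohort collects in at least 40% of participants; risks
#' averaged), `categorization` (all records used; missing recoded as an
#' explicit category), `missing_indicator` (like categorization but
#' continuous factors keep their value plus a missing indicator), and
#' `imputation` (MICE on the training set, coefficient-averaged fits, mean
#' imputation of the query's missing factors at prediction time).
#' @export
STRATEGIES <- c("available_cases", "iterative_bic", "cohort_ensemble",
                "categorization", "missing_indicator", "imputation")

#' Engine-level control parameters
#'
#' @param glm a [logistic_control()].
#' @param m,cycles MICE imputations and cycles per chain.
#' @param seed seed for every stochastic component (MICE).
#' @param allow_interactions stepwise BIC may add two-way interactions.
#' @param max_rounds cap on iterative-BIC restart rounds.
#' @param ensemble_availability minimum fraction of a cohort's participants
#'   with a factor measured for the cohort ensemble to use it (0.4).
#' @export
engine_control <- function(glm = logistic_control(), m = 30L, cycles = 10L,
                           seed = 1L, allow_interactions = TRUE,
                           max_rounds = 12L, ensemble_availability = 0.4) {
  list(glm = glm, m = as.integer(m), cycles = as.integer(cycles),
       seed = as.integer(seed), allow_interactions = allow_interactions,
       max_rounds = as.integer(max_rounds),
       ensemble_availability = ensemble_availability)
}

#' Build a strategy engine over a training set
#'
#' An engine owns whatever the strategy shares across query patterns (the
#' single all-data model for categorization / missing indicator, the MICE
#' imputations and pooled fit for imputation) and caches the tailored
#' per-pattern models, so validating a test set costs one fit per distinct
#' missingness pattern.
#'
#' @param strategy one of [STRATEGIES].
#' @param training a `multi_cohort`.
#' @param control an [engine_control()].
#' @return a `strategy_engine`.
#' @export
strategy_engine <- function(strategy, training, control = engine_control()) {
  strategy <- match.arg(strategy, STRATEGIES)
  stopifnot(inherits(training, "multi_cohort"))
  structure(list(strategy = strategy, training = training,
                 schema = attr(training, "schema"), control = control,
                 cache = new.env(parent = emptyenv()),
                 shared = new.env(parent = emptyenv())),
            class = "strategy_engine")
}

#' @export
print.strategy_engine <- function(x, ...) {
  cat("strategy_engine '", x$strategy, "' over ", length(x$training),
      " cohorts (", length(ls(x$cache)), " pattern models cached)\n",
      sep = "")
  invisible(x)
}

#' Tailored model for one missingness pattern
#'
#' @param engine a [strategy_engine()].
#' @param pattern factor names observed for the query (canonicalized).
#' @return a `pattern_model`.
#' @export
get_pattern_model <- function(engine, pattern) {
  pattern <- as_pattern(pattern, engine$schema)
  key <- pattern_key(pattern)
  got <- engine$cache[[key]]
  if (!is.null(got)) return(got)
  pm <- switch(engine$strategy,
    available_cases = fit_available_cases(engine, pattern),
    iterative_bic = fit_iterative_bic(engine, pattern),
    cohort_ensemble = fit_cohort_ensemble(engine, pattern),
    categorization = fit_all_data(engine, pattern, "categorized"),
    missing_indicator = fit_all_data(engine, pattern, "missing_indicator"),
    imputation = fit_imputation(engine, pattern))
  engine$cache[[key]] <- pm
  pm
}

new_pattern_model <- function(strategy, pattern, effective, payload,
                              n_obs, n_cohorts, schema) {
  structure(list(strategy = strategy, pattern = pattern,
                 effective_pattern = effective, payload = payload,
                 n_obs = n_obs, n_cohorts = n_cohorts, schema = schema),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("pattern_model [", x$strategy, "] pattern={",
      paste(x$pattern, collapse = ","), "}\n  effective={",
      paste(x$effective_pattern, collapse = ","), "}, n_obs=", x$n_obs,
      ", cohorts=", x$n_cohorts, "\n", sep = "")
  invisible(x)
}

fit_available_cases <- function(engine, pattern) {
  pool <- complete_case_subset(engine$training, pattern)
  enc <- encode_raw(pool, pattern, engine$schema)
  model <- tryCatch(
    fit_logistic(enc$x, pool$outcome, engine$control$glm,
                 pattern = pattern),
    patternrisk_insufficient_data = function(e)
      pr_error("patternrisk_insufficient_data",
               paste0("pattern {", paste(pattern, collapse = ","), "}: ",
                      conditionMessage(e))),
    patternrisk_degenerate_outcome = function(e)
      pr_error("patternrisk_insufficient_data",
               paste0("pattern {", paste(pattern, collapse = ","), "}: ",
                      conditionMessage(e))))
  new_pattern_model("available_cases", pattern, pattern,
                    list(model = model), model$n_obs,
                    length(unique(pool$cohort_id)), engine$schema)
}

fit_iterative_bic <- function(engine, pattern) {
  schema <- engine$schema
  mand <- schema_mandatory(schema)
  current <- pattern
  res <- NULL
  pool <- NULL
  for (round in seq_len(engine$control$max_rounds)) {
    pool <- complete_case_subset(engine$training, current)
    enc <- encode_raw(pool, current, schema)
    forced <- enc$terms[!is.na(enc$factor_of) &
                          enc$factor_of %in% mand]
    cand <- setdiff(setdiff(enc$terms, "(Intercept)"), forced)
    res <- stepwise_bic(enc$x, pool$outcome, forced = forced,
                        candidates = cand,
                        allow_interactions = engine$control$allow_interactions,
                        control = engine$control$glm)
    kept_factors <- unique(stats::na.omit(enc$factor_of[
      c(forced, res$selected)]))
    kept <- as_pattern(kept_factors, schema)
    if (setequal(kept, current)) break
    current <- kept  # shrink and re-pool (weakly more complete cases)
  }
  model <- res$model
  model$pattern <- current
  new_pattern_model("iterative_bic", pattern, current,
                    list(model = model, interactions = res$interactions),
                    model$n_obs, length(unique(pool$cohort_id)), schema)
}

cohort_available_factors <- function(cd, schema, min_measured) {
  opt <- schema_optional(schema)
  meas <- vapply(opt, function(nm) mean(!is.na(cd[[nm]])), numeric(1))
  c(schema_mandatory(schema), opt[meas >= min_measured])
}

fit_cohort_ensemble <- function(engine, pattern) {
  schema <- engine$schema
  members <- list()
  for (cd in engine$training) {
    cid <- attr(cd, "cohort_id")
    avail <- cohort_available_factors(cd, schema,
                                      engine$control$ensemble_availability)
    eff <- as_pattern(intersect(pattern, avail), schema)
    sub <- cd[stats::complete.cases(as.data.frame(cd)[, eff, drop = FALSE]),
              , drop = FALSE]
    m <- tryCatch({
      enc <- encode_raw(sub, eff, schema)
      fit_logistic(enc$x, sub$outcome, engine$control$glm, pattern = eff)
    }, patternrisk_error = function(e) {
      warning("cohort '", cid, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(m))
      members[[length(members) + 1L]] <-
        list(cohort_id = cid, model = m, pattern = eff)
  }
  if (!length(members))
    pr_error("patternrisk_ensemble_empty",
             paste0("no cohort could be fit for pattern {",
                    paste(pattern, collapse = ","), "}"))
  eff_union <- as_pattern(unique(unlist(lapply(members, `[[`, "pattern"))),
                          schema)
  new_pattern_model("cohort_ensemble", pattern, eff_union,
                    list(members = members),
                    sum(vapply(members, function(m) m$model$n_obs,
                               numeric(1))),
                    length(members), schema)
}

all_data_shared <- function(engine, coding) {
  key <- paste0("all_data_", coding)
  got <- engine$shared[[key]]
  if (!is.null(got)) return(got)
  pooled <- pool_records(engine$training)
  recode_info <- build_recode_info(pooled, engine$schema, coding)
  enc <- encode_with_recode(pooled, recode_info, engine$schema)
  # drop constant non-intercept columns (e.g. an all-zero indicator)
  keep <- c(TRUE, apply(enc$x[, -1, drop = FALSE], 2,
                        function(v) stats::var(v) > 0))
  if (!all(keep))
    warning("dropped constant design column(s): ",
            paste(colnames(enc$x)[!keep], collapse = ", "))
  x <- enc$x[, keep, drop = FALSE]
  model <- fit_logistic(x, pooled$outcome, engine$control$glm,
                        pattern = schema_factor_names(engine$schema),
                        coding = coding)
  out <- list(model = model, recode_info = recode_info,
              n_cohorts = length(engine$training), n_obs = nrow(pooled))
  engine$shared[[key]] <- out
  out
}

fit_all_data <- function(engine, pattern, coding) {
  sh <- all_data_shared(engine, coding)
  strategy <- if (coding == "categorized") "categorization"
              else "missing_indicator"
  new_pattern_model(strategy, pattern, schema_factor_names(engine$schema),
                    list(model = sh$model, recode_info = sh$recode_info),
                    sh$n_obs, sh$n_cohorts, engine$schema)
}

imputation_shared <- function(engine) {
  got <- engine$shared[["imputation"]]
  if (!is.null(got)) return(got)
  schema <- engine$schema
  pooled <- pool_records(engine$training)
  ctl <- engine$control
  imps <- mice_impute(pooled, schema, m = ctl$m, cycles = ctl$cycles,
                      seed = ctl$seed)
  full <- schema_factor_names(schema)
  fits <- lapply(imps, function(df) {
    enc <- encode_raw(df, full, schema)
    fit_logistic(enc$x, df$outcome, ctl$glm, pattern = full)
  })
  cm <- vapply(fits, `[[`, numeric(length(fits[[1]]$coefficients)),
               "coefficients")
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1)
  coef_bar <- rowMeans(cm)
  wbar <- Reduce(`+`, lapply(fits, `[[`, "vcov")) / length(fits)
  bmat <- if (length(fits) > 1) stats::cov(t(cm)) else 0 * wbar
  pooled_model <- fits[[1]]
  pooled_model$coefficients[] <- coef_bar
  pooled_model$vcov <- wbar + (1 + 1 / length(fits)) * bmat  # Rubin total
  pooled_model$log_likelihood <- mean(vapply(fits, `[[`, numeric(1),
                                             "log_likelihood"))
  marginals <- list()
  for (nm in full) {
    f <- schema_get(schema, nm)
    v <- pooled[[nm]][!is.na(pooled[[nm]])]
    marginals[[nm]] <- if (f$kind == "continuous") {
      if (f$transform == "log2") 2^mean(log2(v)) else mean(v)
    } else names(sort(table(v), decreasing = TRUE))[1]
  }
  out <- list(model = pooled_model, marginals = marginals,
              n_obs = nrow(pooled), n_cohorts = length(engine$training),
              m = length(fits))
  engine$shared[["imputation"]] <- out
  out
}

fit_imputation <- function(engine, pattern) {
  sh <- imputation_shared(engine)
  new_pattern_model("imputation", pattern,
                    schema_factor_names(engine$schema),
                    list(model = sh$model, marginals = sh$marginals,
                         m = sh$m),
                    sh$n_obs, sh$n_cohorts, engine$schema)
}

## ---- one-shot fit interfaces -------------------------------------------

#' Fit one strategy for one pattern
#'
#' Convenience one-shot interfaces; for repeated queries over many patterns
#' build a [strategy_engine()] once instead.
#'
#' @param training a `multi_cohort`.
#' @param pattern observed factor names for the query patient.
#' @param control an [engine_control()].
#' @return a `pattern_model`.
#' @name strategy_fits
NULL

one_shot <- function(strategy, training, pattern, control) {
  get_pattern_model(strategy_engine(strategy, training, control), pattern)
}

#' @rdname strategy_fits
#' @export
available_cases_fit <- function(training, pattern,
                                control = engine_control())
  one_shot("available_cases", training, pattern, control)

#' @rdname strategy_fits
#' @export
iterative_bic_fit <- function(training, pattern,
                              control = engine_control())
  one_shot("iterative_bic", training, pattern, control)

#' @rdname strategy_fits
#' @export
cohort_ensemble_fit <- function(training, pattern,
                                control = engine_control())
  one_shot("cohort_ensemble", training, pattern, control)

#' @rdname strategy_fits
#' @export
categorization_fit <- function(training, pattern = NULL,
                               control = engine_control()) {
  schema <- attr(training, "schema")
  if (is.null(pattern)) pattern <- schema_mandatory(schema)
  one_shot("categorization", training, pattern, control)
}

#' @rdname strategy_fits
#' @export
missing_indicator_fit <- function(training, pattern = NULL,
                                  control = engine_control()) {
  schema <- attr(training, "schema")
  if (is.null(pattern)) pattern <- schema_mandatory(schema)
  one_shot("missing_indicator", training, pattern, control)
}

#' @rdname strategy_fits
#' @export
imputation_fit <- function(training, pattern = NULL,
                           control = engine_control()) {
  schema <- attr(training, "schema")
  if (is.null(pattern)) pattern <- schema_mandatory(schema)
  one_shot("imputation", training, pattern, control)
}

## ---- prediction ---------------------------------------------------------

values_to_row <- function(values, factors, schema) {
  row <- list()
  for (nm in factors) {
    f <- schema_get(schema, nm)
    v <- values[[nm]]
    if (is.null(v) || all(is.na(v))) v <- NA
    row[[nm]] <- if (f$kind == "continuous") as.numeric(v)
                 else as.character(v)
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

validate_query_values <- function(values, schema) {
  unknown <- setdiff(names(values), schema_factor_names(schema))
  if (length(unknown))
    stop("unknown risk factor(s): ", paste(unknown, collapse = ", "))
  for (nm in schema_mandatory(schema)) {
    if (is.null(values[[nm]]) || is.na(values[[nm]]))
      stop("mandatory factor '", nm, "' must be supplied")
  }
  if (!is.null(values$psa) && values$psa <= 0)
    stop("psa must be > 0 ng/mL")
  if (!is.null(values$age) && (values$age < 18 || values$age > 120))
    stop("age must be within [18, 120] years")
  invisible(values)
}

row_with_interactions <- function(enc_row, interactions) {
  if (!length(interactions)) return(enc_row)
  extra <- vapply(interactions, function(key) {
    ab <- strsplit(key, ":", fixed = TRUE)[[1]]
    enc_row[, ab[1]] * enc_row[, ab[2]]
  }, numeric(nrow(enc_row)))
  if (nrow(enc_row) == 1L) extra <- matrix(extra, nrow = 1L,
                                           dimnames = list(NULL, interactions))
  cbind(enc_row, extra)
}

#' Predict risk for one patient from a tailored pattern model
#'
#' Dispatches on the strategy behind the model: single-model strategies
#' encode and predict; the cohort ensemble averages its per-cohort risks;
#' the all-data strategies set unsupplied factors to their missing level
#' (or indicator); imputation fills them from the stored training-set
#' marginals. The returned risk is a proportion strictly inside (0, 1).
#'
#' @param pattern_model a `pattern_model` from [get_pattern_model()] or the
#'   one-shot fitters.
#' @param values named list of the patient's factor values (at minimum the
#'   mandatory factors).
#' @return risk of clinically significant prostate cancer in (0, 1).
#' @export
predict_for_patient <- function(pattern_model, values) {
  pm <- pattern_model
  stopifnot(inherits(pm, "pattern_model"))
  schema <- pm$schema
  validate_query_values(values, schema)
  strategy <- pm$strategy

  if (strategy %in% c("available_cases", "iterative_bic")) {
    need <- pm$effective_pattern
    miss <- need[vapply(need, function(nm) is.null(values[[nm]]) ||
                          all(is.na(values[[nm]])), logical(1))]
    if (length(miss))
      pr_error("patternrisk_contract",
               paste0("factor(s) required by this model are missing: ",
                      paste(miss, collapse = ", ")))
    row <- values_to_row(values, need, schema)
    enc <- encode_raw(row, need, schema)
    x <- row_with_interactions(enc$x, pm$payload$interactions)
    return(unname(predict_proba(pm$payload$model, x)))
  }

  if (strategy == "cohort_ensemble") {
    risks <- vapply(pm$payload$members, function(mb) {
      row <- values_to_row(values, mb$pattern, schema)
      enc <- encode_raw(row, mb$pattern, schema)
      predict_proba(mb$model, enc$x)
    }, numeric(1))
    return(mean(risks))
  }

  if (strategy %in% c("categorization", "missing_indicator")) {
    row <- values_to_row(values, schema_factor_names(schema), schema)
    enc <- encode_with_recode(row, pm$payload$recode_info, schema)
    x <- enc$x[, pm$payload$model$terms, drop = FALSE]
    return(unname(predict_proba(pm$payload$model, x)))
  }

  # imputation: mean / modal fill from training marginals, then predict
  full <- schema_factor_names(schema)
  row <- values_to_row(values, full, schema)
  for (nm in full) {
    if (is.na(row[[nm]])) row[[nm]] <- pm$payload$marginals[[nm]]
  }
  enc <- encode_raw(row, full, schema)
  unname(predict_proba(pm$payload$model, enc$x))
}
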