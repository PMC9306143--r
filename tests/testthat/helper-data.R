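# Small fixtures built in code.

tiny_schema <- function() {
  risk_schema(list(
    risk_factor("psa", "continuous", "log2", mandatory = TRUE),
    risk_factor("age", "continuous", "none", mandatory = TRUE),
    risk_factor("dre", "binary", levels = c("normal", "abnormal")),
    risk_factor("volume", "continuous", "log2"),
    risk_factor("prior_neg_biopsy", "binary", levels = c("no", "yes"))
  ))
}

# Complete records under the tiny schema with a simple logistic truth.
tiny_records <- function(n, seed = 1, beta = c(int = -1.2, psa_log2 = 0.9,
                                               age = 0.04, dre_abnormal = 0.7,
                                               volume_log2 = -1.0,
                                               prior_neg_biopsy_yes = -0.9)) {
  set.seed(seed)
  df <- data.frame(
    psa = exp(log(6) + 0.7 * rnorm(n)),
    age = round(pmin(pmax(64 + 7 * rnorm(n), 35), 90), 1),
    dre = c("normal", "abnormal")[1 + rbinom(n, 1, 0.25)],
    volume = exp(log(40) + 0.45 * rnorm(n)),
    prior_neg_biopsy = c("no", "yes")[1 + rbinom(n, 1, 0.25)],
    stringsAsFactors = FALSE)
  lp <- beta[["int"]] + beta[["psa_log2"]] * log2(df$psa) +
    beta[["age"]] * (df$age - 64) +
    beta[["dre_abnormal"]] * (df$dre == "abnormal") +
    beta[["volume_log2"]] * (log2(df$volume) - log2(40)) +
    beta[["prior_neg_biopsy_yes"]] * (df$prior_neg_biopsy == "yes")
  df$outcome <- rbinom(n, 1, plogis(lp))
  df
}

tiny_cohort <- function(n, seed = 1, cohort_id = "c1", miss = NULL, ...) {
  df <- tiny_records(n, seed, ...)
  if (!is.null(miss)) {
    set.seed(seed + 5000)
    for (nm in names(miss))
      df[[nm]][runif(n) < miss[[nm]]] <- NA
  }
  df$cohort_id <- cohort_id
  cohort_data(df, tiny_schema(), cohort_id = cohort_id)
}

tiny_multicohort <- function(ns = c(400, 300), seeds = seq_along(ns),
                             miss = NULL) {
  multi_cohort(lapply(seq_along(ns), function(i)
    tiny_cohort(ns[i], seed = seeds[i], cohort_id = paste0("c", i),
                miss = if (is.list(miss) && !is.null(names(miss)) &&
                           is.list(miss[[1]])) miss[[i]] else miss)))
}

# One small default-schema scenario reused across tests (cached per session).
small_default_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohorts <- lapply(1:3, function(i)
        cohort_spec(paste0("c", i), c(900, 700, 500)[i],
                    never_collected = list(character(0), "volume",
                                           c("fam_pca_2nd",
                                             "fam_bca_1st"))[[i]],
                    sporadic_rate = c(0.15, 0.25, 0.2)[i]))
      cfg <- synthetic_config(cohorts, seed = 99L)
      m <- calibrate_intercept(default_true_model(), cfg, 0.3,
                               n_sim = 20000L)
      cfg$model <- m
      cache <<- list(config = cfg, data = generate_multicohort(cfg),
                     model = m)
    }
    cache
  }
})
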