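#' True outcome model for synthetic data
#'
#' A `true_model` holds the log-odds-ratio per design term (raw coding of
#' the full 12-factor pattern) plus an intercept, and is used to simulate
#' clinically significant prostate cancer outcomes.
#'
#' @param coefficients named numeric vector of log odds ratios; names must
#'   be raw-coding term names (e.g. `psa_log2`, `dre_abnormal`).
#' @param intercept log-odds intercept.
#' @export
true_model <- function(coefficients, intercept = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(is.finite(coefficients)), is.finite(intercept))
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "true_model")
}

#' Default true model: the published full-model odds ratios
#'
#' Log odds ratios of the 12-factor full model reported for the pooled
#' complete-case fit: age 1.07 per year, PSA 2.38 per doubling, prostate
#' volume 0.25 per doubling, abnormal DRE 1.95, prior negative biopsy 0.32,
#' African ancestry 0.68, Hispanic ethnicity 1.08, 5-ARI use 0.96, prior
#' PSA screen 0.71, first-degree prostate-cancer family history 1.93,
#' second-degree 1.30, first-degree breast-cancer family history 1.15.
#' The intercept is 0 pending [calibrate_intercept()].
#'
#' @return a [true_model()].
#' @export
default_true_model <- function() {
  or <- c(psa_log2 = 2.38, age = 1.07, dre_abnormal = 1.95,
          volume_log2 = 0.25, prior_neg_biopsy_yes = 0.32,
          fiveari_yes = 0.96, prior_psa_screen_yes = 0.71,
          african_ancestry_yes = 0.68, hispanic_yes = 1.08,
          fam_pca_1st_yes = 1.93, fam_pca_2nd_yes = 1.30,
          fam_bca_1st_yes = 1.15)
  true_model(log(or), intercept = 0)
}

#' Per-cohort generative law
#'
#' Continuous covariates are drawn from a Gaussian copula with modest
#' positive correlation between PSA, age and prostate volume (log-normal
#' PSA and volume, normal age); binary factors are independent Bernoulli.
#'
#' @param cohort_id identifier.
#' @param n cohort size.
#' @param psa_meanlog,psa_sdlog log-normal PSA parameters (ng/mL).
#' @param age_mean,age_sd normal age parameters (years; clipped to
#'   \[30, 95\]).
#' @param vol_meanlog,vol_sdlog log-normal prostate volume parameters (cc).
#' @param binary_probs named probabilities of the non-reference level for
#'   each binary factor.
#' @param never_collected optional factors this cohort never collects
#'   (systematic missingness; erased for every record).
#' @param sporadic_rate patient-level missingness probability in \[0, 1)
#'   applied to each collected optional factor.
#' @export
cohort_spec <- function(cohort_id, n, psa_meanlog = log(6), psa_sdlog = 0.7,
                        age_mean = 64, age_sd = 7, vol_meanlog = log(40),
                        vol_sdlog = 0.45,
                        binary_probs = default_binary_probs(),
                        never_collected = character(0),
                        sporadic_rate = 0) {
  stopifnot(n >= 1, sporadic_rate >= 0, sporadic_rate < 1)
  list(cohort_id = as.character(cohort_id), n = as.integer(n),
       psa_meanlog = psa_meanlog, psa_sdlog = psa_sdlog,
       age_mean = age_mean, age_sd = age_sd, vol_meanlog = vol_meanlog,
       vol_sdlog = vol_sdlog, binary_probs = binary_probs,
       never_collected = never_collected, sporadic_rate = sporadic_rate)
}

default_binary_probs <- function() {
  c(dre = 0.25, prior_neg_biopsy = 0.25, fiveari = 0.10,
    prior_psa_screen = 0.65, african_ancestry = 0.12, hispanic = 0.08,
    fam_pca_1st = 0.15, fam_pca_2nd = 0.10, fam_bca_1st = 0.10)
}

#' Synthetic multi-cohort configuration
#'
#' @param cohorts list of [cohort_spec()]s.
#' @param model a [true_model()].
#' @param mechanism `"MCAR"` (each collected optional cell erased
#'   independently at the cohort's sporadic rate) or `"MAR"` (erasure
#'   probability depends logistically on the always-observed PSA and age,
#'   with the per-factor intercept solved so the marginal rate matches the
#'   cohort's sporadic rate).
#' @param mar_slopes logistic slopes of the MAR law on `log2(PSA) -
#'   log2(6)` and `(age - 65)/10`.
#' @param copula_corr correlations `c(psa_age, psa_vol, age_vol)` of the
#'   Gaussian copula for the continuous covariates.
#' @param schema the [risk_schema()] generated data conform to.
#' @param seed integer seed making generation fully reproducible.
#' @export
synthetic_config <- function(cohorts, model = default_true_model(),
                             mechanism = c("MCAR", "MAR"),
                             mar_slopes = c(psa = 0.6, age = 0.4),
                             copula_corr = c(psa_age = 0.2, psa_vol = 0.3,
                                             age_vol = 0.15),
                             schema = default_schema(), seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(cohorts) >= 1)
  mand <- schema_mandatory(schema)
  for (cs in cohorts) {
    if (any(mand %in% cs$never_collected))
      stop("config error: mandatory factors cannot be never_collected")
  }
  ids <- vapply(cohorts, `[[`, character(1), "cohort_id")
  if (anyDuplicated(ids)) stop("config error: duplicate cohort ids")
  structure(list(cohorts = cohorts, model = model, mechanism = mechanism,
                 mar_slopes = mar_slopes, copula_corr = copula_corr,
                 schema = schema, seed = as.integer(seed)),
            class = "synthetic_config")
}

draw_covariates <- function(n, cs, config) {
  r <- config$copula_corr
  R <- matrix(c(1, r[["psa_age"]], r[["psa_vol"]],
                r[["psa_age"]], 1, r[["age_vol"]],
                r[["psa_vol"]], r[["age_vol"]], 1), 3, 3)
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
  df <- data.frame(
    psa = exp(cs$psa_meanlog + cs$psa_sdlog * z[, 1]),
    age = pmin(pmax(cs$age_mean + cs$age_sd * z[, 2], 30), 95),
    volume = exp(cs$vol_meanlog + cs$vol_sdlog * z[, 3]))
  schema <- config$schema
  for (nm in setdiff(schema_factor_names(schema), names(df))) {
    f <- schema_get(schema, nm)
    p <- cs$binary_probs[[nm]]
    if (is.null(p)) stop("no generative probability for '", nm, "'")
    df[[nm]] <- f$levels[1 + stats::rbinom(n, 1, p)]
  }
  df[, schema_factor_names(schema), drop = FALSE]
}

#' Linear predictor and true risk under a true model
#' @param records complete records (data.frame).
#' @param model a [true_model()].
#' @param schema a [risk_schema()].
#' @name true_risk
#' @export
true_linear_predictor <- function(records, model, schema = default_schema()) {
  enc <- encode_raw(records, schema_factor_names(schema), schema)
  nm <- names(model$coefficients)
  missing_terms <- setdiff(nm, enc$terms)
  if (length(missing_terms))
    stop("true model names unknown terms: ",
         paste(missing_terms, collapse = ", "))
  model$intercept + drop(enc$x[, nm, drop = FALSE] %*% model$coefficients)
}

#' @rdname true_risk
#' @export
true_risk <- function(records, model, schema = default_schema()) {
  stats::plogis(true_linear_predictor(records, model, schema))
}

#' Calibrate the true-model intercept to a target prevalence
#'
#' Simulates covariates from the configured cohort mixture (sizes as
#' weights) under a fixed internal seed and solves, by monotone 1-D root
#' finding, for the intercept that makes the expected outcome prevalence
#' match `target`.
#'
#' @param model a [true_model()].
#' @param config a [synthetic_config()].
#' @param target prevalence in (0, 1).
#' @param n_sim covariate draws used for the Monte-Carlo expectation.
#' @return the model with its intercept replaced.
#' @export
calibrate_intercept <- function(model, config, target, n_sim = 100000L) {
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("unattainable target prevalence: ", target)
  sizes <- vapply(config$cohorts, `[[`, integer(1), "n")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed + 999983L)
  ns <- pmax(1L, round(n_sim * sizes / sum(sizes)))
  recs <- do.call(rbind, lapply(seq_along(config$cohorts), function(i)
    draw_covariates(ns[i], config$cohorts[[i]], config)))
  m0 <- model; m0$intercept <- 0
  lp0 <- true_linear_predictor(recs, m0, config$schema)
  f <- function(a) mean(stats::plogis(lp0 + a)) - target
  a <- stats::uniroot(f, c(-40, 40), tol = 1e-9)$root
  model$intercept <- a
  model
}

solve_mar_intercept <- function(shift, rate) {
  if (rate <= 0) return(-Inf)
  f <- function(a) mean(stats::plogis(a + shift)) - rate
  stats::uniroot(f, c(-30, 30), tol = 1e-9)$root
}

#' Generate a synthetic multi-cohort dataset
#'
#' Per cohort: draw covariates from the cohort's generative law, draw
#' outcomes Bernoulli(plogis(linear predictor under the true model)), then
#' erase cells -- factors in `never_collected` for every row; otherwise
#' each collected optional cell independently at the sporadic rate (MCAR)
#' or with the MAR logistic probability. The family-history pair is erased
#' jointly (one shared draw) so the pair stays jointly observed or jointly
#' missing. Outcomes and mandatory factors are never missing. Fully
#' reproducible from `config$seed`; the pre-erasure table of each cohort is
#' retained as `attr(cohort, "complete")`.
#'
#' @param config a [synthetic_config()].
#' @return a `multi_cohort`.
#' @export
generate_multicohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  schema <- config$schema
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)
  cohorts <- lapply(config$cohorts, function(cs) {
    df <- draw_covariates(cs$n, cs, config)
    p <- true_risk(df, config$model, schema)
    df <- cbind(cohort_id = cs$cohort_id,
                outcome = stats::rbinom(cs$n, 1, p), df,
                stringsAsFactors = FALSE)
    complete <- df
    optional <- schema_optional(schema)
    erase <- matrix(FALSE, cs$n, length(optional),
                    dimnames = list(NULL, optional))
    for (nm in optional) {
      if (nm %in% cs$never_collected) { erase[, nm] <- TRUE; next }
      rate <- cs$sporadic_rate
      if (rate <= 0) next
      if (nm == FAMHX_PAIR[2] && FAMHX_PAIR[1] %in% optional &&
          !FAMHX_PAIR[1] %in% cs$never_collected) {
        erase[, nm] <- erase[, FAMHX_PAIR[1]]  # joint with its pair
        next
      }
      if (config$mechanism == "MCAR") {
        erase[, nm] <- stats::runif(cs$n) < rate
      } else {
        shift <- config$mar_slopes[["psa"]] * (log2(df$psa) - log2(6)) +
          config$mar_slopes[["age"]] * (df$age - 65) / 10
        a0 <- solve_mar_intercept(shift, rate)
        erase[, nm] <- stats::runif(cs$n) < stats::plogis(a0 + shift)
      }
    }
    for (nm in optional) df[[nm]][erase[, nm]] <- NA
    cd <- cohort_data(df, schema, cohort_id = cs$cohort_id)
    attr(cd, "complete") <- complete
    cd
  })
  multi_cohort(cohorts)
}

#' The default study scenario
#'
#' A miniature of the multi-cohort design the package targets: 10 training
#' cohorts of heterogeneous size (250--3,000 records, about 12,650 total)
#' and prevalence, with cohort-level systematic non-collection of some
#' optional factors plus sporadic patient-level missingness of 20--40%,
#' and one held-out validation cohort (n = 2,000) with a shifted covariate
#' distribution (higher PSA, older) yielding a higher prevalence (~0.32 vs
#' ~0.28 in training) while the same outcome model holds, plus light (5%)
#' sporadic missingness. The global intercept is calibrated so pooled
#' training prevalence is 0.28.
#'
#' @param seed integer; drives every random draw.
#' @param mechanism `"MCAR"` (default) or `"MAR"`.
#' @return list with `training` (`multi_cohort`), `validation`
#'   (`cohort_data`), `model` (calibrated [true_model()]), and the two
#'   configs.
#' @export
default_scenario <- function(seed = 1L, mechanism = "MCAR") {
  sizes <- c(3000, 2400, 1800, 1500, 1200, 900, 700, 500, 400, 250)
  psa_shift <- c(0.15, 0.10, 0.05, 0, -0.05, -0.10, 0.12, -0.08, 0.06, -0.12)
  age_shift <- c(2, 1, 0, -1, -2, 1.5, -1.5, 0.5, -0.5, 0)
  sporadic <- c(0.20, 0.25, 0.30, 0.35, 0.40, 0.22, 0.28, 0.33, 0.38, 0.24)
  pair <- FAMHX_PAIR
  never <- list(character(0), "prior_psa_screen", "volume", pair,
                c("volume", "fiveari"), c(pair, "prior_psa_screen"),
                character(0), "hispanic", c("volume", pair), character(0))
  cohorts <- lapply(1:10, function(i)
    cohort_spec(paste0("cohort_", sprintf("%02d", i)), sizes[i],
                psa_meanlog = log(6) + psa_shift[i],
                age_mean = 64 + age_shift[i],
                never_collected = never[[i]], sporadic_rate = sporadic[i]))
  cfg <- synthetic_config(cohorts, mechanism = mechanism, seed = seed)
  model <- calibrate_intercept(default_true_model(), cfg, target = 0.28)
  cfg$model <- model

  val_spec <- cohort_spec("validation", 2000,
                          psa_meanlog = log(6) + 0.15, age_mean = 66.5,
                          sporadic_rate = 0.05)
  val_cfg <- synthetic_config(list(val_spec), model = model,
                              mechanism = mechanism, schema = cfg$schema,
                              seed = seed + 104729L)
  training <- generate_multicohort(cfg)
  validation <- generate_multicohort(val_cfg)[[1]]
  list(training = training, validation = validation, model = model,
       config = cfg, validation_config = val_cfg)
}
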