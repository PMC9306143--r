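#' Calibration-in-the-large with 95% CI
#'
#' CIL = 100 * (mean predicted risk - observed event rate), as a signed
#' percentage: negative values mean the model under-predicts. The CI uses a
#' normal approximation on the per-patient differences.
#'
#' @param risks predicted risks in (0, 1).
#' @param outcomes 0/1 outcomes.
#' @param conf confidence level.
#' @return list with `cil`, `ci` (length 2), `n`.
#' @export
cil_with_ci <- function(risks, outcomes, conf = 0.95) {
  stopifnot(length(risks) == length(outcomes), length(risks) > 0,
            all(outcomes %in% c(0, 1)), all(risks > 0 & risks < 1))
  d <- risks - outcomes
  cil <- 100 * mean(d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- 100 * stats::sd(d) / sqrt(length(d))
  if (is.na(se)) se <- 0
  list(cil = cil, ci = c(cil - z * se, cil + z * se), n = length(d))
}

#' AUC (Mann-Whitney concordance) with DeLong 95% CI
#'
#' The probability that a random case outranks a random non-case, ties
#' counted one half, reported as a percentage; the CI uses DeLong's
#' placement-value variance.
#'
#' @inheritParams cil_with_ci
#' @return list with `auc` (percentage), `ci`, `n_cases`, `n_controls`.
#' @export
auc_with_ci <- function(risks, outcomes, conf = 0.95) {
  stopifnot(length(risks) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  cases <- risks[outcomes == 1]
  controls <- risks[outcomes == 0]
  n1 <- length(cases); n0 <- length(controls)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r_all <- rank(c(cases, controls), ties.method = "average")
  r1 <- rank(cases, ties.method = "average")
  r0 <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r1) / n0            # placement of each case
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r0) / n1   # placement of controls
  auc <- mean(v10)
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  if (is.na(v)) v <- 0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = 100 * auc, ci = 100 * ci, n_cases = n1, n_controls = n0)
}

#' Wilson score interval for a binomial proportion
#' @param k successes, `n` trials.
#' @param n number of trials.
#' @param conf confidence level.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Decile calibration curve
#'
#' Records are stably sorted by predicted risk and split into `n_bins`
#' near-equal bins (any remainder goes to the leading bins); each bin
#' reports the mean predicted risk, observed event proportion, Wilson
#' pointwise CI and count.
#'
#' @inheritParams cil_with_ci
#' @param n_bins number of bins (default deciles).
#' @param conf pointwise confidence level.
#' @return a `calibration_curve` data.frame.
#' @export
calibration_curve <- function(risks, outcomes, n_bins = 10, conf = 0.95) {
  n <- length(risks)
  stopifnot(length(outcomes) == n, all(outcomes %in% c(0, 1)))
  if (n < n_bins) stop("fewer points (", n, ") than bins (", n_bins, ")")
  ord <- order(risks)  # stable radix sort: ties keep input order
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  stop_at <- cumsum(sizes)
  start_at <- c(1, stop_at[-n_bins] + 1)
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- ord[start_at[b]:stop_at[b]]
    k <- sum(outcomes[idx])
    ci <- wilson_ci(k, length(idx), conf)
    data.frame(bin = b, n = length(idx), mean_predicted = mean(risks[idx]),
               observed = k / length(idx), lower = ci[["lower"]],
               upper = ci[["upper"]])
  })
  structure(do.call(rbind, rows), class = c("calibration_curve",
                                            "data.frame"))
}

#' @export
plot.calibration_curve <- function(x, ...) {
  lim <- range(0, x$mean_predicted, x$upper)
  plot(x$mean_predicted, x$observed, xlim = lim, ylim = lim,
       xlab = "Mean predicted risk", ylab = "Observed proportion",
       pch = 19, ...)
  graphics::polygon(c(x$mean_predicted, rev(x$mean_predicted)),
                    c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$mean_predicted, x$observed, col = "steelblue")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' External validation of a strategy on a held-out cohort
#'
#' For each test patient the observed-factor pattern is derived, the
#' strategy's tailored model is obtained (cached per pattern inside the
#' engine), and the risk is predicted; CIL, AUC and the decile calibration
#' curve are then computed over the served patients. Patients whose
#' pattern cannot be served are reported in `$unserved`, never silently
#' dropped.
#'
#' @param strategy a strategy name (see [STRATEGIES]) or a prebuilt
#'   [strategy_engine()].
#' @param training a `multi_cohort` (ignored when an engine is given).
#' @param test a [cohort_data()] disjoint from training.
#' @param control an [engine_control()].
#' @param n_bins calibration bins.
#' @return a `validation_report`.
#' @export
external_validate <- function(strategy, training, test,
                              control = engine_control(), n_bins = 10) {
  engine <- if (inherits(strategy, "strategy_engine")) strategy
            else strategy_engine(strategy, training, control)
  schema <- engine$schema
  stopifnot(inherits(test, "cohort_data"))
  if (!inherits(strategy, "strategy_engine") &&
      attr(test, "cohort_id") %in% names(engine$training))
    stop("test cohort '", attr(test, "cohort_id"),
         "' is part of the training set")
  df <- as.data.frame(test)
  n <- nrow(df)
  risks <- rep(NA_real_, n)
  unserved <- list()
  fns <- schema_factor_names(schema)
  keys <- apply(!is.na(as.data.frame(df)[, fns, drop = FALSE]), 1,
                function(obs) pattern_key(fns[obs]))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    pattern <- strsplit(key, "+", fixed = TRUE)[[1]]
    pm <- tryCatch(get_pattern_model(engine, pattern),
                   patternrisk_error = function(e) e)
    if (inherits(pm, "condition")) {
      unserved[[length(unserved) + 1L]] <-
        data.frame(row = idx, pattern = key,
                   reason = conditionMessage(pm))
      next
    }
    for (i in idx) {
      vals <- as.list(df[i, fns])
      vals <- vals[!vapply(vals, is.na, logical(1))]
      risks[i] <- predict_for_patient(pm, vals)
    }
  }
  served <- !is.na(risks)
  if (!any(served)) stop("no test patient could be served")
  y <- df$outcome[served]
  r <- risks[served]
  report <- structure(list(
    strategy = engine$strategy,
    cil = cil_with_ci(r, y),
    auc = auc_with_ci(r, y),
    calibration = calibration_curve(r, y, n_bins = min(n_bins, length(r))),
    n_test = n, n_served = sum(served), prevalence = mean(y),
    risks = risks, outcomes = df$outcome,
    n_patterns = length(unique(keys)),
    unserved = if (length(unserved)) do.call(rbind, unserved) else NULL,
    cohort_id = attr(test, "cohort_id")),
    class = "validation_report")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report [", x$strategy, "] on '", x$cohort_id, "' (n=",
      x$n_test, ", prevalence ", sprintf("%.3f", x$prevalence), ")\n",
      sep = "")
  cat(sprintf("  CIL %5.1f%% (95%% CI %5.1f, %5.1f)\n", x$cil$cil,
              x$cil$ci[1], x$cil$ci[2]))
  cat(sprintf("  AUC %5.1f%% (95%% CI %5.1f, %5.1f)\n", x$auc$auc,
              x$auc$ci[1], x$auc$ci[2]))
  if (!is.null(x$unserved))
    cat("  unserved patients:", nrow(x$unserved), "\n")
  invisible(x)
}

#' Serialize / restore a validation report (lossless JSON round trip)
#' @param report a `validation_report`.
#' @param path file path.
#' @name report_io
#' @export
write_report_json <- function(report, path) {
  obj <- unclass(report)
  obj$calibration <- as.data.frame(obj$calibration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname report_io
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$calibration <- structure(as.data.frame(obj$calibration),
                               class = c("calibration_curve", "data.frame"))
  structure(obj, class = "validation_report")
}

#' Leave-one-cohort-out cross-validation
#'
#' Each cohort in turn is held out as the test set while the strategy is
#' trained on the remaining cohorts; the summary gives the median and IQR
#' of CIL and AUC across completed folds. A fold that fails entirely is
#' recorded as failed (with a warning) and excluded from the summary.
#'
#' @inheritParams external_validate
#' @return a `cv_result` with `$folds` (one `validation_report` per
#'   held-out cohort, or a condition for failed folds) and `$summary`.
#' @export
loco_cv <- function(strategy, training, control = engine_control(),
                    n_bins = 10) {
  stopifnot(inherits(training, "multi_cohort"), length(training) >= 2)
  ids <- names(training)
  folds <- lapply(ids, function(id) {
    rest <- multi_cohort(training[setdiff(ids, id)])
    tryCatch(external_validate(strategy, rest, training[[id]],
                               control = control, n_bins = n_bins),
             error = function(e) {
               warning("fold '", id, "' failed: ", conditionMessage(e))
               e
             })
  })
  names(folds) <- ids
  ok <- vapply(folds, inherits, logical(1), "validation_report")
  cils <- vapply(folds[ok], function(f) f$cil$cil, numeric(1))
  aucs <- vapply(folds[ok], function(f) f$auc$auc, numeric(1))
  summ <- list(
    cil_median = stats::median(cils), cil_iqr = unname(stats::IQR(cils)),
    auc_median = stats::median(aucs), auc_iqr = unname(stats::IQR(aucs)),
    n_folds = length(folds), n_completed = sum(ok))
  structure(list(folds = folds, summary = summ,
                 strategy = if (inherits(strategy, "strategy_engine"))
                   strategy$strategy else strategy),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat("cv_result [", x$strategy, "]: ", s$n_completed, "/", s$n_folds,
      " folds completed\n", sep = "")
  cat(sprintf("  CIL median %5.1f%% (IQR %.1f)\n", s$cil_median, s$cil_iqr))
  cat(sprintf("  AUC median %5.1f%% (IQR %.1f)\n", s$auc_median, s$auc_iqr))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, metric = c("cil", "auc"), ...) {
  metric <- match.arg(metric)
  ok <- vapply(x$folds, inherits, logical(1), "validation_report")
  v <- vapply(x$folds[ok], function(f)
    if (metric == "cil") f$cil$cil else f$auc$auc, numeric(1))
  graphics::boxplot(v, horizontal = TRUE,
                    xlab = paste(toupper(metric), "(%)"), ...)
  graphics::stripchart(v, add = TRUE, pch = 19, method = "jitter",
                       col = "steelblue")
  invisible(x)
}
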