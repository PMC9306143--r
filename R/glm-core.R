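#' Control parameters for logistic fitting
#'
#' @param epsilon IRLS relative-deviance convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @param min_obs,min_events,min_nonevents minimum fit size; below any of
#'   these an insufficient-data error is raised. The defaults are
#'   deliberately low because small centres are kept, not excluded.
#' @param ridge optional ridge stabilizer added to the information matrix
#'   (0 = plain maximum likelihood). Intended for degenerate inputs only.
#' @export
logistic_control <- function(epsilon = 1e-12, maxit = 100L, min_obs = 25L,
                             min_events = 5L, min_nonevents = 5L,
                             ridge = 0) {
  list(epsilon = epsilon, maxit = as.integer(maxit),
       min_obs = as.integer(min_obs), min_events = as.integer(min_events),
       min_nonevents = as.integer(min_nonevents), ridge = ridge)
}

pr_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "patternrisk_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS fit (via [stats::glm.fit()]) of `Pr(y = 1) = plogis(x %*% beta)`,
#' with covariance from the inverse observed information. Degenerate
#' outcomes (single class), insufficient sample size and perfect separation
#' raise classed errors (`patternrisk_degenerate_outcome`,
#' `patternrisk_insufficient_data`, `patternrisk_separation`) so callers can
#' react per policy.
#'
#' @param x design matrix including an intercept column.
#' @param y 0/1 outcome vector.
#' @param control a [logistic_control()].
#' @param pattern,coding optional provenance recorded on the fit.
#' @return an object of class `fitted_logistic` with elements `terms`,
#'   `coefficients` (log-odds scale), `vcov`, `log_likelihood`, `n_obs`,
#'   `n_events`, `converged`, `pattern`, `coding`.
#' @export
fit_logistic <- function(x, y, control = logistic_control(),
                         pattern = NULL, coding = "raw") {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  n <- nrow(x)
  ev <- sum(y)
  if (ev == 0 || ev == n)
    pr_error("patternrisk_degenerate_outcome",
             "degenerate outcome: only one outcome class present")
  if (n < control$min_obs || ev < control$min_events ||
      n - ev < control$min_nonevents)
    pr_error("patternrisk_insufficient_data",
             sprintf(paste0("insufficient data: n=%d, events=%d, ",
                            "non-events=%d (need >= %d/%d/%d)"),
                     n, ev, n - ev, control$min_obs, control$min_events,
                     control$min_nonevents))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))

  if (control$ridge > 0) {
    fit <- ridge_logistic(x, y, control)
    beta <- fit$beta; mu <- fit$mu; converged <- fit$converged
    info <- fit$info
  } else {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(x, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = control$epsilon,
                                                  maxit = control$maxit)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    beta <- fit$coefficients
    if (anyNA(beta))
      pr_error("patternrisk_separation",
               paste0("design is rank deficient; aliased term(s): ",
                      paste(colnames(x)[is.na(beta)], collapse = ", ")),
               terms = colnames(x)[is.na(beta)])
    mu <- fit$fitted.values
    converged <- fit$converged
    big <- abs(beta) > 15
    if (sep_warn && any(big))
      pr_error("patternrisk_separation",
               paste0("perfect or quasi-perfect separation; diverging ",
                      "term(s): ", paste(colnames(x)[big], collapse = ", ")),
               terms = colnames(x)[big])
    w <- mu * (1 - mu)
    info <- crossprod(x * sqrt(w))
  }

  vcov <- tryCatch(chol2inv(chol(info)),
                   error = function(e)
                     pr_error("patternrisk_separation",
                              "information matrix is singular",
                              terms = colnames(x)))
  dimnames(vcov) <- list(colnames(x), colnames(x))
  mu_cl <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu_cl) + (1 - y) * log(1 - mu_cl))
  structure(list(terms = colnames(x), coefficients = stats::setNames(beta, colnames(x)),
                 vcov = vcov, log_likelihood = ll, n_obs = n, n_events = as.integer(ev),
                 converged = converged, pattern = pattern, coding = coding),
            class = "fitted_logistic")
}

# Newton with a ridge penalty on the information matrix; used only as an
# optional stabilizer for degenerate inputs.
ridge_logistic <- function(x, y, control) {
  p <- ncol(x)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(control$maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(x * sqrt(w)) + diag(control$ridge, p)
    score <- crossprod(x, y - mu)
    beta <- beta + drop(solve(info, score))
    mu2 <- pmin(pmax(stats::plogis(drop(x %*% beta)), 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu2) + (1 - y) * log(1 - mu2))
    if (abs(dev - dev_old) / (abs(dev) + 0.1) < control$epsilon) {
      converged <- TRUE; break
    }
    dev_old <- dev
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  list(beta = stats::setNames(beta, colnames(x)), mu = mu,
       converged = converged,
       info = crossprod(x * sqrt(mu * (1 - mu))) + diag(control$ridge, p))
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat("fitted_logistic: ", length(x$terms), " terms, n=", x$n_obs,
      " (", x$n_events, " events), logLik=", sprintf("%.2f", x$log_likelihood),
      "\n", sep = "")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(coef = x$coefficients, OR = exp(x$coefficients), se = se)
  print(round(tab, 4))
  invisible(x)
}

#' Predicted risk for encoded rows
#'
#' Inverse-logit of the linear predictor, clipped so the result is strictly
#' inside (0, 1) even for extreme inputs.
#'
#' @param model a `fitted_logistic`.
#' @param newx matrix (or single named vector) whose columns cover the
#'   model's terms.
#' @return numeric vector of risks in (0, 1).
#' @export
predict_proba <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1,
                                         dimnames = list(NULL, names(newx)))
  missing_terms <- setdiff(model$terms, colnames(newx))
  if (length(missing_terms))
    pr_error("patternrisk_contract",
             paste0("prediction rows lack model term(s): ",
                    paste(missing_terms, collapse = ", ")))
  lp <- drop(as.matrix(newx[, model$terms, drop = FALSE]) %*%
               model$coefficients)
  bound <- stats::qlogis(1e-12)
  stats::plogis(pmin(pmax(lp, bound), -bound))
}

#' Bayesian information criterion of a fit
#'
#' `-2 * logLik + p * log(n)` where `p` counts all estimated coefficients,
#' intercept included. Within a fixed-data model comparison the intercept
#' convention only shifts every BIC by the same constant, so selection is
#' unaffected.
#'
#' @param model a converged `fitted_logistic`.
#' @export
bic <- function(model) {
  stopifnot(inherits(model, "fitted_logistic"))
  if (!isTRUE(model$converged)) stop("BIC requires a converged model")
  -2 * model$log_likelihood + length(model$coefficients) * log(model$n_obs)
}
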