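#' Multiple imputation by chained equations
#'
#' Fully conditional specification on the pooled training records: missing
#' cells are initialized by draws from the observed marginals, then, per
#' cycle and per incomplete factor in schema order, a type-appropriate
#' conditional model (Bayesian linear regression on the log2 scale for
#' continuous factors, logistic regression for binary factors) is fit on
#' the rows where the factor was originally observed, using every other
#' factor plus the outcome as covariates, and the missing cells are redrawn
#' from the fitted predictive distribution. `m` independent chains are run
#' for `cycles` cycles each, fully seeded.
#'
#' @param records pooled data.frame with `outcome` and all schema factors;
#'   outcomes must be complete.
#' @param schema a [risk_schema()].
#' @param m number of imputations (chains).
#' @param cycles cycles per chain.
#' @param seed integer seed.
#' @return list of `m` completed data.frames (same shape as `records`).
#' @export
mice_impute <- function(records, schema, m = 30L, cycles = 10L, seed = 1L) {
  stopifnot(is.data.frame(records), m >= 1, cycles >= 1)
  if (anyNA(records$outcome)) stop("outcomes must be complete")
  fns <- schema_factor_names(schema)
  obs_mask <- lapply(fns, function(nm) !is.na(records[[nm]]))
  names(obs_mask) <- fns
  incomplete <- fns[vapply(obs_mask, function(mk) any(!mk), logical(1))]
  for (nm in incomplete) {
    if (!any(obs_mask[[nm]]))
      pr_error("patternrisk_cannot_impute",
               paste0("factor '", nm, "' has no observed values"))
  }
  if (!length(incomplete))
    return(replicate(m, records, simplify = FALSE))

  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  # numeric working copy: continuous on transformed scale, binary as 0/1
  to_work <- function(df) {
    w <- data.frame(outcome = as.numeric(df$outcome))
    for (nm in fns) {
      f <- schema_get(schema, nm)
      w[[nm]] <- if (f$kind == "continuous") transform_value(f, df[[nm]])
                 else as.numeric(df[[nm]] == f$levels[2])
    }
    w
  }
  from_work <- function(w) {
    out <- records
    for (nm in incomplete) {
      f <- schema_get(schema, nm)
      mis <- !obs_mask[[nm]]
      out[[nm]][mis] <- if (f$kind == "continuous") {
        if (f$transform == "log2") 2^w[[nm]][mis] else w[[nm]][mis]
      } else f$levels[1 + (w[[nm]][mis] > 0.5)]
    }
    out
  }

  work0 <- to_work(records)
  lapply(seq_len(m), function(chain) {
    w <- work0
    for (nm in incomplete) {
      mis <- !obs_mask[[nm]]
      w[[nm]][mis] <- sample(w[[nm]][obs_mask[[nm]]], sum(mis),
                             replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (nm in incomplete) {
        mis <- !obs_mask[[nm]]
        xcols <- c("outcome", setdiff(fns, nm))
        X <- cbind(1, as.matrix(w[, xcols, drop = FALSE]))
        yv <- w[[nm]]
        f <- schema_get(schema, nm)
        drawn <- impute_draw(X[!mis, , drop = FALSE], yv[!mis],
                             X[mis, , drop = FALSE],
                             binary = f$kind != "continuous")
        w[[nm]][mis] <- drawn
      }
    }
    from_work(w)
  })
}

# One predictive draw for the missing rows of a factor. Falls back to a
# marginal draw when the conditional model cannot be fit (degenerate or
# separated data).
impute_draw <- function(X_obs, y_obs, X_mis, binary) {
  n_mis <- nrow(X_mis)
  marginal <- function() sample(y_obs, n_mis, replace = TRUE)
  if (n_mis == 0L) return(numeric(0))
  # drop constant columns (beyond the intercept) to keep X full rank
  keep <- c(TRUE, apply(X_obs[, -1, drop = FALSE], 2,
                        function(v) stats::var(v) > 0))
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  p <- ncol(X_obs)
  if (nrow(X_obs) <= p + 1) return(marginal())
  if (binary) {
    tryCatch({
      if (length(unique(y_obs)) < 2) return(marginal())
      fit <- suppressWarnings(
        stats::glm.fit(X_obs, y_obs, family = stats::binomial(),
                       control = stats::glm.control(maxit = 50)))
      beta <- fit$coefficients
      if (anyNA(beta)) return(marginal())
      W <- fit$fitted.values * (1 - fit$fitted.values)
      V <- chol2inv(chol(crossprod(X_obs * sqrt(W)) + diag(1e-8, p)))
      bstar <- beta + drop(t(chol(V + diag(1e-12, p))) %*% stats::rnorm(p))
      stats::rbinom(n_mis, 1, stats::plogis(drop(X_mis %*% bstar)))
    }, error = function(e) marginal())
  } else {
    tryCatch({
      qrX <- qr(X_obs)
      if (qrX$rank < p) return(marginal())
      beta <- qr.coef(qrX, y_obs)
      res <- y_obs - drop(X_obs %*% beta)
      df <- nrow(X_obs) - p
      sigma2 <- sum(res^2) / stats::rchisq(1, df)
      R <- qr.R(qrX)
      V <- chol2inv(R)  # (X'X)^{-1}
      bstar <- beta + drop(t(chol(V + diag(1e-12, p))) %*%
                             stats::rnorm(p)) * sqrt(sigma2)
      drop(X_mis %*% bstar) + stats::rnorm(n_mis, 0, sqrt(sigma2))
    }, error = function(e) marginal())
  }
}
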