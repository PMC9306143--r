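# Independent oracles, implemented from first principles and kept separate
# from the package's fitting/metric code paths.

# Plain Newton-Raphson maximum-likelihood logistic regression.
newton_logistic_oracle <- function(x, y, tol = 1e-12, maxit = 200) {
  x <- as.matrix(x)
  beta <- numeric(ncol(x))
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(x, y - mu))
    hess <- crossprod(x, x * (mu * (1 - mu)))
    step <- solve(hess, score)
    beta <- beta + step
    if (max(abs(score)) < tol && max(abs(step)) < 1e-10) break
  }
  unname(beta)
}

# Exhaustive concordant/discordant/tied pair enumeration.
auc_pair_oracle <- function(risks, outcomes) {
  cases <- risks[outcomes == 1]
  controls <- risks[outcomes == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Exhaustive all-subsets BIC search over main effects (no interactions).
exhaustive_bic_oracle <- function(x, y, forced, candidates,
                                  control = logistic_control()) {
  best <- NULL
  k <- length(candidates)
  for (mask in 0:(2^k - 1)) {
    sel <- candidates[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    b <- tryCatch({
      m <- fit_logistic(x[, c(forced, sel), drop = FALSE], y, control)
      bic(m)
    }, error = function(e) Inf)
    if (is.null(best) || b < best$bic) best <- list(bic = b, selected = sel)
  }
  best
}
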