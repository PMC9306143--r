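#' Pre-fit the per-pattern submodel library
#'
#' Enumerates every subset of the optional factors (2^k patterns for k
#' optional factors; 1,024 for the default 10) and fits the chosen
#' strategy's tailored model for each, so a deployed risk tool can answer
#' any query pattern by lookup. Patterns whose fit fails the minimum-size
#' guard are stored as explicit unserved entries carrying the reason. Each
#' served entry is smoke-tested on a median/modal training patient.
#'
#' @param training a `multi_cohort`.
#' @param strategy strategy to pre-fit (default `available_cases`, the
#'   strategy deployed by the published tool).
#' @param control an [engine_control()].
#' @return a `pattern_library`.
#' @export
build_pattern_library <- function(training, strategy = "available_cases",
                                  control = engine_control()) {
  engine <- strategy_engine(strategy, training, control)
  schema <- engine$schema
  optional <- sort(schema_optional(schema))
  mandatory <- schema_mandatory(schema)
  k <- length(optional)
  smoke <- smoke_query(training, schema)
  entries <- list()
  for (mask in 0:(2^k - 1)) {
    subset <- optional[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    pattern <- as_pattern(c(mandatory, subset), schema)
    key <- pattern_key(pattern)
    pm <- tryCatch(get_pattern_model(engine, pattern),
                   patternrisk_error = function(e) e)
    if (inherits(pm, "condition")) {
      if (!length(subset))
        stop("mandatory-only pattern could not be fit; library unusable: ",
             conditionMessage(pm))
      entries[[key]] <- list(served = FALSE, key = key, pattern = pattern,
                             reason = conditionMessage(pm))
      next
    }
    risk <- predict_for_patient(pm, smoke[pattern])
    if (!is.finite(risk) || risk <= 0 || risk >= 1)
      stop("smoke prediction failed for pattern {", key, "}")
    entries[[key]] <- list(served = TRUE, key = key, pattern = pattern,
                           pm = pm, n_obs = pm$n_obs,
                           n_cohorts = pm$n_cohorts)
  }
  structure(list(strategy = engine$strategy, schema = schema,
                 optional_factors = optional, entries = entries,
                 provenance = list(
                   training_digest = rlang::hash(pool_records(training)),
                   seed = control$seed,
                   built_at = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(
                     utils::packageVersion("patternrisk")))),
            class = "pattern_library")
}

# a complete "typical" patient assembled from training marginals
smoke_query <- function(training, schema) {
  pooled <- pool_records(training)
  out <- list()
  for (nm in schema_factor_names(schema)) {
    f <- schema_get(schema, nm)
    v <- pooled[[nm]][!is.na(pooled[[nm]])]
    out[[nm]] <- if (f$kind == "continuous") stats::median(v)
                 else names(sort(table(v), decreasing = TRUE))[1]
  }
  out
}

#' @export
print.pattern_library <- function(x, ...) {
  served <- vapply(x$entries, `[[`, logical(1), "served")
  cat("pattern_library [", x$strategy, "]: ", length(x$entries),
      " patterns (", sum(served), " served, ", sum(!served),
      " unserved)\n", sep = "")
  cat("  built ", x$provenance$built_at, ", training digest ",
      x$provenance$training_digest, "\n", sep = "")
  invisible(x)
}

## ---- serialization ------------------------------------------------------

serialize_fitted <- function(m) {
  list(terms = m$terms,
       coef_hex = sprintf("%a", unname(m$coefficients)),
       coefficients = unname(m$coefficients),
       n_obs = m$n_obs, n_events = m$n_events)
}

deserialize_fitted <- function(s) {
  beta <- as.numeric(unlist(s$coef_hex))
  structure(list(terms = unlist(s$terms),
                 coefficients = stats::setNames(beta, unlist(s$terms)),
                 vcov = NULL, log_likelihood = NA_real_,
                 n_obs = as.integer(s$n_obs),
                 n_events = as.integer(s$n_events), converged = TRUE,
                 pattern = NULL, coding = "raw"),
            class = "fitted_logistic")
}

serialize_pattern_model <- function(pm) {
  p <- pm$payload
  out <- list(strategy = pm$strategy, pattern = pm$pattern,
              effective_pattern = pm$effective_pattern, n_obs = pm$n_obs,
              n_cohorts = pm$n_cohorts)
  if (!is.null(p$model)) out$model <- serialize_fitted(p$model)
  if (!is.null(p$interactions)) out$interactions <- p$interactions
  if (!is.null(p$marginals)) out$marginals <- p$marginals
  if (!is.null(p$recode_info))
    out$recode_info <- list(coding = p$recode_info$coding,
                            blocks = p$recode_info$blocks)
  if (!is.null(p$members))
    out$members <- lapply(p$members, function(mb)
      list(cohort_id = mb$cohort_id, pattern = mb$pattern,
           model = serialize_fitted(mb$model)))
  out
}

deserialize_pattern_model <- function(s, schema) {
  payload <- list()
  if (!is.null(s$model)) payload$model <- deserialize_fitted(s$model)
  if (!is.null(s$interactions)) payload$interactions <- unlist(s$interactions)
  if (!is.null(s$marginals)) payload$marginals <- s$marginals
  if (!is.null(s$recode_info))
    payload$recode_info <- structure(
      list(coding = s$recode_info$coding,
           blocks = lapply(s$recode_info$blocks, function(b) {
             b$levels <- unlist(b$levels)
             b$sources <- unlist(b$sources)
             b
           })),
      class = "recode_info")
  if (!is.null(s$members))
    payload$members <- lapply(s$members, function(mb)
      list(cohort_id = mb$cohort_id, pattern = unlist(mb$pattern),
           model = deserialize_fitted(mb$model)))
  new_pattern_model(s$strategy, unlist(s$pattern),
                    unlist(s$effective_pattern), payload,
                    as.integer(s$n_obs), as.integer(s$n_cohorts), schema)
}

library_payload_digest <- function(entries) {
  parts <- vapply(entries, function(e) {
    if (!isTRUE(e$served)) return(paste0(e$key, "|unserved"))
    s <- if (!is.null(e$pm)) serialize_pattern_model(e$pm) else e$serialized
    paste0(e$key, "|", paste(unlist(s$model$coef_hex), collapse = ","))
  }, character(1))
  rlang::hash(paste(parts, collapse = ";"))
}

#' Save / load a pattern library as JSON
#'
#' Coefficients are stored both in decimal (for humans) and as hex floats,
#' so a loaded library reproduces predictions bit-identically. A format
#' version and a payload digest are checked on load.
#'
#' @param library a `pattern_library`.
#' @param path file path.
#' @name library_io
#' @export
save_library <- function(library, path) {
  stopifnot(inherits(library, "pattern_library"))
  entries <- lapply(library$entries, function(e) {
    if (!isTRUE(e$served))
      return(list(served = FALSE, key = e$key, pattern = e$pattern,
                  reason = e$reason))
    list(served = TRUE, key = e$key, pattern = e$pattern,
         n_obs = e$n_obs, n_cohorts = e$n_cohorts,
         model = serialize_pattern_model(e$pm))
  })
  obj <- list(format = "patternrisk_library", format_version = 1L,
              strategy = library$strategy,
              optional_factors = library$optional_factors,
              schema = lapply(library$schema$factors, function(f)
                f[c("name", "kind", "transform", "mandatory", "levels")]),
              provenance = library$provenance,
              payload_digest = library_payload_digest(library$entries),
              entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname library_io
#' @export
load_library <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("load error: malformed library file: ",
                         conditionMessage(e)))
  if (!identical(obj$format, "patternrisk_library"))
    stop("load error: not a patternrisk library file")
  if (!identical(as.integer(obj$format_version), 1L))
    stop("load error: unsupported library format version ",
         obj$format_version)
  schema <- risk_schema(lapply(obj$schema, function(f)
    risk_factor(f$name, f$kind, f$transform %||% "none",
                isTRUE(f$mandatory), unlist(f$levels))))
  entries <- lapply(obj$entries, function(e) {
    if (!isTRUE(e$served))
      return(list(served = FALSE, key = e$key,
                  pattern = unlist(e$pattern), reason = e$reason))
    list(served = TRUE, key = e$key, pattern = unlist(e$pattern),
         n_obs = as.integer(e$n_obs), n_cohorts = as.integer(e$n_cohorts),
         pm = deserialize_pattern_model(e$model, schema),
         serialized = e$model)
  })
  names(entries) <- vapply(entries, `[[`, character(1), "key")
  lib <- structure(list(strategy = obj$strategy, schema = schema,
                        optional_factors = unlist(obj$optional_factors),
                        entries = entries, provenance = obj$provenance),
                   class = "pattern_library")
  if (!identical(library_payload_digest(entries), obj$payload_digest))
    stop("load error: payload digest mismatch (file corrupted?)")
  lib
}

## ---- query --------------------------------------------------------------

#' Answer a risk query from the pattern library
#'
#' The supplied factor set is canonicalized to a pattern key and the
#' matching pre-fit submodel is looked up and applied. The answer carries
#' transparency metadata: the pattern used, the training sample size and
#' cohort count behind the model, the model terms with odds ratios, and
#' any supplied factor the model did not use.
#'
#' @param library a `pattern_library`.
#' @param query named list: `psa` (ng/mL) and `age` (years) are mandatory,
#'   plus any subset of the optional factors.
#' @return a `risk_answer` with the risk as a percentage.
#' @export
predict_risk <- function(library, query) {
  stopifnot(inherits(library, "pattern_library"))
  schema <- library$schema
  validate_query_values(query, schema)
  supplied <- names(query)[!vapply(query, function(v)
    is.null(v) || all(is.na(v)), logical(1))]
  pattern <- as_pattern(supplied, schema)
  key <- pattern_key(pattern)
  entry <- library$entries[[key]]
  if (is.null(entry))
    stop("pattern {", key, "} is not in the library")
  if (!isTRUE(entry$served)) {
    sub <- nearest_served_subpattern(library, pattern)
    stop("pattern {", key, "} could not be served (", entry$reason,
         "); nearest served sub-pattern: {", sub, "}")
  }
  pm <- entry$pm
  risk <- predict_for_patient(pm, query)
  used <- pm$effective_pattern
  terms_tab <- if (!is.null(pm$payload$model)) {
    data.frame(term = pm$payload$model$terms,
               coefficient = unname(pm$payload$model$coefficients),
               odds_ratio = exp(unname(pm$payload$model$coefficients)))
  } else NULL
  structure(list(risk_percent = 100 * risk, risk = risk, pattern = pattern,
                 pattern_key = key, n_obs = entry$n_obs,
                 n_cohorts = entry$n_cohorts, terms = terms_tab,
                 unused_factors = setdiff(pattern, used),
                 strategy = library$strategy),
            class = "risk_answer")
}

nearest_served_subpattern <- function(library, pattern) {
  served <- Filter(function(e) isTRUE(e$served), library$entries)
  subs <- Filter(function(e) all(e$pattern %in% pattern), served)
  if (!length(subs)) return("<none>")
  sizes <- vapply(subs, function(e) length(e$pattern), integer(1))
  best <- subs[sizes == max(sizes)]
  best <- best[order(vapply(best, `[[`, character(1), "key"))]
  best[[1]]$key
}

#' @export
print.risk_answer <- function(x, ...) {
  cat(sprintf("Risk of clinically significant prostate cancer: %.2f%%\n",
              x$risk_percent))
  cat("  strategy ", x$strategy, "; pattern {",
      paste(x$pattern, collapse = ","), "}\n", sep = "")
  cat("  model behind the answer: n=", x$n_obs, " from ", x$n_cohorts,
      " cohort(s)\n", sep = "")
  if (length(x$unused_factors))
    cat("  supplied but unused:", paste(x$unused_factors, collapse = ", "),
        "\n")
  if (!is.null(x$terms)) {
    cat("  terms (odds ratios):\n")
    tab <- x$terms
    tab$odds_ratio <- round(tab$odds_ratio, 3)
    tab$coefficient <- round(tab$coefficient, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Per-pattern inspection table
#' @param library a `pattern_library`.
#' @return data.frame with one row per pattern.
#' @export
inspect_library <- function(library) {
  rows <- lapply(library$entries, function(e)
    data.frame(key = e$key, served = isTRUE(e$served),
               n_optional = length(e$pattern) - 2L,
               n_obs = if (isTRUE(e$served)) e$n_obs else NA_integer_,
               n_cohorts = if (isTRUE(e$served)) e$n_cohorts
                           else NA_integer_,
               reason = if (isTRUE(e$served)) "" else e$reason,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$n_optional, out$key), ]
}
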