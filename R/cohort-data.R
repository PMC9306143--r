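#' Cohort datasets
#'
#' A `cohort_data` object is one centre's biopsy table: a data.frame with
#' columns `cohort_id`, `outcome` (0/1, never missing; 1 = clinically
#' significant prostate cancer) and one column per schema factor. Missing
#' optional values are `NA`; mandatory factors are never missing. A
#' `multi_cohort` is a list of `cohort_data` sharing one schema.
#'
#' @param df data.frame with the columns above.
#' @param schema a [risk_schema()].
#' @param cohort_id cohort identifier; defaults to the (unique) value of the
#'   `cohort_id` column.
#' @param on_invalid `"reject"` drops rows violating record invariants,
#'   attaching row-indexed diagnostics as `attr(x, "rejected")` with a
#'   warning; `"error"` stops at the first violation.
#' @return `cohort_data`: a validated data.frame with attributes `schema`
#'   and `cohort_id`.
#' @export
cohort_data <- function(df, schema, cohort_id = NULL,
                        on_invalid = c("reject", "error")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(df), inherits(schema, "risk_schema"))
  if (!"outcome" %in% names(df)) stop("column 'outcome' is required")
  if (is.null(cohort_id)) {
    if (!"cohort_id" %in% names(df))
      stop("cohort_id not given and no 'cohort_id' column present")
    ids <- unique(df$cohort_id)
    if (length(ids) != 1L)
      stop("data contain ", length(ids),
           " cohort ids; a cohort_data holds exactly one")
    cohort_id <- as.character(ids)
  }
  missing_cols <- setdiff(schema_factor_names(schema), names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))

  out <- data.frame(cohort_id = rep(as.character(cohort_id), nrow(df)),
                    outcome = as.integer(df$outcome),
                    stringsAsFactors = FALSE)
  for (nm in schema_factor_names(schema)) {
    f <- schema_get(schema, nm)
    out[[nm]] <- if (f$kind == "continuous") as.numeric(df[[nm]])
                 else as.character(df[[nm]])
  }

  diag <- validate_records(out, schema)
  if (nrow(diag)) {
    if (on_invalid == "error")
      stop("validation error: row ", diag$row[1], ": ", diag$reason[1])
    warning("rejected ", length(unique(diag$row)), " row(s); see attr(x, 'rejected')")
    out <- out[-unique(diag$row), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(out) < 1L) stop("cohort '", cohort_id, "' has no valid records")
  structure(out, schema = schema, cohort_id = cohort_id,
            rejected = if (nrow(diag)) diag else NULL,
            class = c("cohort_data", "data.frame"))
}

# Row-indexed invariant diagnostics; empty data.frame when all rows valid.
validate_records <- function(df, schema) {
  bad <- list()
  note <- function(rows, reason) {
    if (length(rows)) bad[[length(bad) + 1L]] <<- data.frame(
      row = rows, reason = reason, stringsAsFactors = FALSE)
  }
  note(which(is.na(df$outcome)), "outcome is missing")
  note(which(!is.na(df$outcome) & !df$outcome %in% c(0L, 1L)),
       "outcome is not 0/1")
  for (nm in schema_factor_names(schema)) {
    f <- schema_get(schema, nm)
    v <- df[[nm]]
    if (f$mandatory) note(which(is.na(v)),
                          paste0("mandatory factor '", nm, "' is missing"))
    if (f$kind == "continuous") {
      if (f$transform == "log2")
        note(which(!is.na(v) & v <= 0),
             paste0("'", nm, "' must be > 0 (log2 scale)"))
      if (nm == "age")
        note(which(!is.na(v) & (v < 18 | v > 120)),
             "'age' outside [18, 120]")
    } else {
      note(which(!is.na(v) & !v %in% f$levels),
           paste0("'", nm, "' has a level outside [",
                  paste(f$levels, collapse = "/"), "]"))
    }
  }
  if (!length(bad))
    return(data.frame(row = integer(), reason = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, bad)
  out[order(out$row), , drop = FALSE]
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data '", attr(x, "cohort_id"), "': ", nrow(x), " records, ",
      sum(x$outcome), " events (prevalence ",
      sprintf("%.3f", mean(x$outcome)), ")\n", sep = "")
  invisible(x)
}

#' Bundle cohorts sharing one schema
#'
#' @param cohorts list of [cohort_data()] objects with unique cohort ids.
#' @return a `multi_cohort` object (list of cohorts, `schema` attribute).
#' @export
multi_cohort <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  ok <- vapply(cohorts, inherits, logical(1), "cohort_data")
  if (!all(ok)) stop("all elements must be cohort_data objects")
  ids <- vapply(cohorts, attr, character(1), "cohort_id")
  if (anyDuplicated(ids)) stop("duplicate cohort ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(cohorts) <- ids
  structure(cohorts, schema = attr(cohorts[[1]], "schema"),
            class = "multi_cohort")
}

#' @export
print.multi_cohort <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat("multi_cohort: ", length(x), " cohorts, ", sum(n), " records total\n",
      sep = "")
  for (cd in x) print(cd)
  invisible(x)
}

#' Pool a multi_cohort into one data.frame (cohort order, then row order)
#' @param data a `multi_cohort`.
#' @export
pool_records <- function(data) {
  stopifnot(inherits(data, "multi_cohort"))
  out <- do.call(rbind, lapply(data, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Read one cohort from CSV
#'
#' The file must have a header naming `outcome`, `cohort_id` (unless
#' `cohort_id` is supplied) and every schema factor. Missing cells are empty
#' or any string in `na_strings`.
#'
#' @inheritParams cohort_data
#' @param path CSV file path.
#' @param na_strings sentinels treated as missing (default empty cell and
#'   `"NA"`).
#' @return a [cohort_data()]; rejected rows (if any) are reported in
#'   `attr(x, "rejected")`.
#' @export
read_cohort_csv <- function(path, schema, cohort_id = NULL,
                            na_strings = c("", "NA"),
                            on_invalid = c("reject", "error")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(c("outcome", schema_factor_names(schema)), names(raw))
  if (length(missing_cols))
    stop("schema error in '", path, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (nm in names(raw)) raw[[nm]][raw[[nm]] %in% na_strings] <- NA
  for (nm in schema_factor_names(schema)) {
    f <- schema_get(schema, nm)
    if (f$kind == "continuous") {
      v <- suppressWarnings(as.numeric(raw[[nm]]))
      bad <- which(is.na(v) & !is.na(raw[[nm]]))
      if (length(bad))
        stop("parse error in '", path, "', column '", nm, "', row ", bad[1],
             ": '", raw[[nm]][bad[1]], "' is not numeric")
      raw[[nm]] <- v
    }
  }
  v <- suppressWarnings(as.numeric(raw$outcome))
  bad <- which(is.na(v) & !is.na(raw$outcome))
  if (length(bad))
    stop("parse error in '", path, "', column 'outcome', row ", bad[1])
  raw$outcome <- v
  cohort_data(raw, schema, cohort_id = cohort_id,
              on_invalid = match.arg(on_invalid))
}

#' Write a cohort to CSV (round-trips with [read_cohort_csv()])
#' @param data a [cohort_data()].
#' @param path output file.
#' @param na sentinel written for missing cells.
#' @export
write_cohort_csv <- function(data, path, na = "") {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = na)
  invisible(path)
}

#' Read / write a multi-cohort set as one CSV keyed by `cohort_id`
#' @inheritParams read_cohort_csv
#' @export
read_multicohort_csv <- function(path, schema, na_strings = c("", "NA"),
                                 on_invalid = c("reject", "error")) {
  on_invalid <- match.arg(on_invalid)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!"cohort_id" %in% names(raw)) stop("column 'cohort_id' is required")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  ids <- unique(raw$cohort_id)
  cohorts <- lapply(ids, function(id) {
    utils::write.csv(raw[raw$cohort_id == id, , drop = FALSE], tmp,
                     row.names = FALSE, na = "")
    read_cohort_csv(tmp, schema, cohort_id = id, na_strings = na_strings,
                    on_invalid = on_invalid)
  })
  multi_cohort(cohorts)
}

#' @rdname read_multicohort_csv
#' @param data a `multi_cohort`.
#' @param na sentinel for missing cells.
#' @export
write_multicohort_csv <- function(data, path, na = "") {
  utils::write.csv(pool_records(data), path, row.names = FALSE, na = na)
  invisible(path)
}

#' Per-cohort, per-factor fraction of missing values
#'
#' Mandatory factors always report 0 (they can never be missing).
#'
#' @param data a `multi_cohort` or single `cohort_data`.
#' @return data.frame with columns `cohort_id`, `factor`, `frac_missing`.
#' @export
missingness_summary <- function(data) {
  if (inherits(data, "cohort_data")) data <- multi_cohort(list(data))
  stopifnot(inherits(data, "multi_cohort"))
  schema <- attr(data, "schema")
  rows <- lapply(data, function(cd) {
    data.frame(cohort_id = attr(cd, "cohort_id"),
               factor = schema_factor_names(schema),
               frac_missing = vapply(schema_factor_names(schema),
                                     function(nm) mean(is.na(cd[[nm]])),
                                     numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled complete cases for a pattern
#'
#' Returns, in stable order (cohort order then row order), every record
#' across all cohorts for which each factor in `pattern` is observed.
#'
#' @param data a `multi_cohort`.
#' @param pattern character vector of factor names (canonicalized with
#'   [as_pattern()]).
#' @return pooled data.frame (possibly 0 rows).
#' @export
complete_case_subset <- function(data, pattern) {
  stopifnot(inherits(data, "multi_cohort"))
  schema <- attr(data, "schema")
  pattern <- as_pattern(pattern, schema)
  pooled <- pool_records(data)
  keep <- rep(TRUE, nrow(pooled))
  for (nm in pattern) keep <- keep & !is.na(pooled[[nm]])
  out <- pooled[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Missingness pattern of one patient record or query
#'
#' @param values named list or one-row data.frame of factor values (NA or
#'   absent = missing).
#' @param schema a [risk_schema()].
#' @return canonical pattern (character vector).
#' @export
derive_pattern <- function(values, schema) {
  values <- as.list(values)
  nms <- intersect(schema_factor_names(schema), names(values))
  obs <- nms[!vapply(nms, function(nm) is.null(values[[nm]]) ||
                       all(is.na(values[[nm]])), logical(1))]
  miss_mand <- setdiff(schema_mandatory(schema), obs)
  if (length(miss_mand))
    stop("mandatory factor(s) missing: ", paste(miss_mand, collapse = ", "))
  as_pattern(obs, schema)
}
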