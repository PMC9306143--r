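#' Risk-factor schema
#'
#' A `risk_schema` is the ordered list of predictors a risk model may use.
#' Each factor has a kind (`"continuous"`, `"binary"` or `"categorical"`),
#' an encoding transform (`"none"` or `"log2"`), a mandatory flag, and, for
#' non-continuous factors, an ordered level vector whose first element is the
#' reference level.
#'
#' Exactly two factors must be mandatory; mandatory factors can never be
#' missing in any record or query.
#'
#' @param factors list of factor descriptors built with [risk_factor()].
#' @return an object of class `risk_schema`.
#' @seealso [default_schema()] for the 12-predictor prostate-biopsy schema.
#' @export
risk_schema <- function(factors) {
  stopifnot(is.list(factors), length(factors) > 0)
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate factor names in schema: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  s <- structure(list(factors = factors), class = "risk_schema")
  names(s$factors) <- nm
  mand <- schema_mandatory(s)
  if (length(mand) != 2L)
    stop("a risk_schema must have exactly 2 mandatory factors, got ",
         length(mand))
  for (f in factors) {
    if (f$kind == "continuous" && length(f$levels))
      stop("continuous factor '", f$name, "' must not declare levels")
    if (f$kind != "continuous") {
      if (length(f$levels) < 2L) stop("factor '", f$name,
                                      "' needs at least 2 levels")
      if (anyDuplicated(f$levels)) stop("duplicate levels for '", f$name, "'")
      if (f$transform != "none")
        stop("transform applies to continuous factors only ('", f$name, "')")
    }
    if (f$kind == "binary" && length(f$levels) != 2L)
      stop("binary factor '", f$name, "' must have exactly 2 levels")
  }
  s
}

#' Describe one risk factor
#'
#' @param name identifier (used as CSV column name).
#' @param kind `"continuous"`, `"binary"` or `"categorical"`.
#' @param transform `"none"` or `"log2"` (continuous only; log2 requires
#'   strictly positive values).
#' @param mandatory logical; mandatory factors must be observed everywhere.
#' @param levels ordered level vector, reference first (non-continuous only).
#' @export
risk_factor <- function(name, kind = c("continuous", "binary", "categorical"),
                        transform = c("none", "log2"), mandatory = FALSE,
                        levels = NULL) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(name = name, kind = kind, transform = transform,
       mandatory = isTRUE(mandatory), levels = levels)
}

#' The default 12-predictor prostate-biopsy schema
#'
#' Two mandatory predictors (serum PSA in ng/mL, modeled per doubling on the
#' log2 scale, and age in years, untransformed) and ten optional ones:
#' digital rectal exam (normal/abnormal), prostate volume in cc (log2),
#' prior negative biopsy, 5-alpha-reductase-inhibitor use, prior PSA screen,
#' African ancestry, Hispanic ethnicity, first- and second-degree prostate
#' cancer family history, and first-degree breast cancer family history.
#' The outcome these factors predict is clinically significant prostate
#' cancer, i.e. biopsy Gleason grade group >= 2.
#'
#' @return a [risk_schema()].
#' @export
default_schema <- function() {
  yn <- c("no", "yes")
  risk_schema(list(
    risk_factor("psa", "continuous", "log2", mandatory = TRUE),
    risk_factor("age", "continuous", "none", mandatory = TRUE),
    risk_factor("dre", "binary", levels = c("normal", "abnormal")),
    risk_factor("volume", "continuous", "log2"),
    risk_factor("prior_neg_biopsy", "binary", levels = yn),
    risk_factor("fiveari", "binary", levels = yn),
    risk_factor("prior_psa_screen", "binary", levels = yn),
    risk_factor("african_ancestry", "binary", levels = yn),
    risk_factor("hispanic", "binary", levels = yn),
    risk_factor("fam_pca_1st", "binary", levels = yn),
    risk_factor("fam_pca_2nd", "binary", levels = yn),
    risk_factor("fam_bca_1st", "binary", levels = yn)
  ))
}

#' @export
print.risk_schema <- function(x, ...) {
  cat("risk_schema with", length(x$factors), "factors\n")
  for (f in x$factors) {
    cat(sprintf("  %-18s %-11s %-5s %s%s\n", f$name, f$kind,
                if (f$transform == "none") "" else f$transform,
                if (f$mandatory) "mandatory" else "optional",
                if (length(f$levels))
                  paste0("  [", paste(f$levels, collapse = "/"), "]") else ""))
  }
  invisible(x)
}

#' Schema accessors
#'
#' Factor names of a schema, in schema order; the mandatory pair; and the
#' optional factors.
#'
#' @param schema a [risk_schema()].
#' @return character vector of factor names.
#' @name schema_accessors
#' @export
schema_factor_names <- function(schema) names(schema$factors)

#' @rdname schema_accessors
#' @export
schema_mandatory <- function(schema) {
  names(schema$factors)[vapply(schema$factors, `[[`, logical(1), "mandatory")]
}

#' @rdname schema_accessors
#' @export
schema_optional <- function(schema) {
  setdiff(schema_factor_names(schema), schema_mandatory(schema))
}

schema_get <- function(schema, name) {
  f <- schema$factors[[name]]
  if (is.null(f)) stop("unknown factor '", name, "'")
  f
}

#' Canonicalize a missingness pattern
#'
#' A pattern is the subset of schema factors observed for a query patient.
#' Canonical form: schema order, always containing both mandatory factors.
#'
#' @param observed character vector of observed factor names (mandatory
#'   factors are added if absent).
#' @param schema a [risk_schema()].
#' @return character vector in schema order.
#' @export
as_pattern <- function(observed, schema) {
  observed <- unique(as.character(observed))
  unknown <- setdiff(observed, schema_factor_names(schema))
  if (length(unknown))
    stop("pattern names factors not in schema: ",
         paste(unknown, collapse = ", "))
  observed <- union(observed, schema_mandatory(schema))
  intersect(schema_factor_names(schema), observed)
}

#' Canonical key for a pattern (sorted factor names)
#' @param pattern character vector of factor names.
#' @export
pattern_key <- function(pattern) paste(sort(unique(pattern)), collapse = "+")

#' Read / write a schema as a YAML config
#'
#' @param path file path.
#' @name schema_io
#' @export
read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  risk_schema(lapply(y$factors, function(f) {
    risk_factor(f$name, f$kind, f$transform %||% "none",
                isTRUE(f$mandatory), unlist(f$levels))
  }))
}

#' @rdname schema_io
#' @param schema a [risk_schema()].
#' @export
write_schema_yaml <- function(schema, path) {
  yaml::write_yaml(list(factors = lapply(schema$factors, function(f) {
    f[c("name", "kind", "transform", "mandatory", "levels")]
  })), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
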