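#' Stratify prostate volume
#'
#' Volume in cc is stratified to `<30`, `30-50` (closed interval) and `>50`,
#' with a fourth level for missing values, so that it can be supplied from a
#' pre-biopsy DRE or TRUS estimate.
#'
#' @param v numeric vector of volumes (cc) or `NA`.
#' @return character vector with levels `lt30`, `30to50`, `gt50`, `missing`.
#' @export
categorize_volume <- function(v) {
  if (any(!is.na(v) & v <= 0)) stop("volume must be > 0 cc")
  out <- rep("missing", length(v))
  out[!is.na(v) & v < 30] <- "lt30"
  out[!is.na(v) & v >= 30 & v <= 50] <- "30to50"
  out[!is.na(v) & v > 50] <- "gt50"
  out
}

#' Combine the jointly-collected family-history pair
#'
#' Second-degree prostate-cancer and first-degree breast-cancer family
#' history are either both collected by a cohort or neither; giving each its
#' own missing level would be collinear, so they are combined into one
#' 5-level factor.
#'
#' @param second_degree_pca,first_degree_bca character vectors with values
#'   `"yes"`, `"no"` or `NA`; the two must be jointly observed or jointly
#'   missing element-wise.
#' @return character vector with levels `none`, `pca2_only`, `bca1_only`,
#'   `both`, `missing` (reference `none`).
#' @export
combine_family_history <- function(second_degree_pca, first_degree_bca) {
  a <- as.character(second_degree_pca)
  b <- as.character(first_degree_bca)
  stopifnot(length(a) == length(b))
  bad <- xor(is.na(a), is.na(b))
  if (any(bad))
    stop("consistency error: family-history pair must be jointly observed ",
         "or jointly missing (first violation at element ", which(bad)[1], ")")
  chk <- function(x) if (any(!is.na(x) & !x %in% c("yes", "no")))
    stop("family-history values must be yes/no/NA")
  chk(a); chk(b)
  out <- rep("missing", length(a))
  out[!is.na(a) & a == "no"  & b == "no"]  <- "none"
  out[!is.na(a) & a == "yes" & b == "no"]  <- "pca2_only"
  out[!is.na(a) & a == "no"  & b == "yes"] <- "bca1_only"
  out[!is.na(a) & a == "yes" & b == "yes"] <- "both"
  out
}

FAMHX_PAIR <- c("fam_pca_2nd", "fam_bca_1st")
FAMHX_LEVELS <- c("none", "pca2_only", "bca1_only", "both", "missing")
VOLUME_LEVELS <- c("lt30", "30to50", "gt50", "missing")

transformed_name <- function(f) {
  if (f$transform == "log2") paste0(f$name, "_log2") else f$name
}

transform_value <- function(f, v) {
  if (f$transform == "log2") {
    if (any(!is.na(v) & v <= 0))
      stop("encoding error: '", f$name, "' must be > 0 under log2")
    log2(v)
  } else v
}

# Recode plan for the all-data codings. Built from training records so the
# kept levels reflect what the data can identify; empty levels are dropped
# (and unseen levels at prediction map to "missing" with a warning).
build_recode_info <- function(records, schema,
                              coding = c("categorized", "missing_indicator")) {
  coding <- match.arg(coding)
  blocks <- list()
  combine_pair <- all(FAMHX_PAIR %in% schema_factor_names(schema)) &&
    (anyNA(records[[FAMHX_PAIR[1]]]) || anyNA(records[[FAMHX_PAIR[2]]]))
  add <- function(b) blocks[[length(blocks) + 1L]] <<- b
  keep_levels <- function(vals, all_levels) {
    kept <- all_levels[all_levels %in% unique(vals)]
    # reference level is always retained so dummies have a baseline
    union(all_levels[1], kept)
  }
  for (nm in schema_factor_names(schema)) {
    f <- schema_get(schema, nm)
    if (combine_pair && nm %in% FAMHX_PAIR) {
      if (nm == FAMHX_PAIR[1]) {
        vals <- combine_family_history(records[[FAMHX_PAIR[1]]],
                                       records[[FAMHX_PAIR[2]]])
        add(list(type = "combined_famhx", name = "famhx2",
                 sources = FAMHX_PAIR,
                 levels = keep_levels(vals, FAMHX_LEVELS)))
      }
      next
    }
    if (f$kind == "continuous") {
      if (f$mandatory) {
        add(list(type = "cont", name = nm))
      } else if (coding == "categorized") {
        if (nm != "volume")
          stop("no categorization rule for optional continuous factor '",
               nm, "'")
        vals <- categorize_volume(records[[nm]])
        add(list(type = "cat_volume", name = nm,
                 levels = keep_levels(vals, VOLUME_LEVELS)))
      } else {
        has_missing <- anyNA(records[[nm]])
        if (!has_missing)
          warning("'", nm, "' has no missing values; indicator dropped")
        add(list(type = "mi_cont", name = nm, has_missing = has_missing))
      }
    } else {
      lv <- c(f$levels, "missing")
      vals <- ifelse(is.na(records[[nm]]), "missing",
                     as.character(records[[nm]]))
      add(list(type = "cat", name = nm, levels = keep_levels(vals, lv),
               base_levels = f$levels))
    }
  }
  structure(list(coding = coding, blocks = blocks), class = "recode_info")
}

# Map one categorical block's raw values to kept levels. Unseen levels map
# to "missing" with a warning; if the training data had no missing level
# for this factor (it was always collected), a missing query value falls
# back to the reference level instead.
map_to_kept <- function(vals, kept, name) {
  out <- vals
  unseen <- !out %in% kept
  if (any(unseen)) {
    target <- if ("missing" %in% kept) "missing" else kept[1]
    warning("level '", unique(out[unseen])[1], "' of '", name,
            "' not identifiable from training; mapped to '", target, "'")
    out[unseen] <- target
  }
  out
}

dummy_cols <- function(vals, kept, prefix) {
  non_ref <- kept[-1]
  m <- vapply(non_ref, function(l) as.numeric(vals == l),
              numeric(length(vals)))
  if (length(vals) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- paste0(prefix, "_", non_ref)
  m
}

encode_with_recode <- function(records, recode_info, schema) {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  factor_of <- c(`(Intercept)` = NA_character_)
  for (b in recode_info$blocks) {
    if (b$type == "cont") {
      f <- schema_get(schema, b$name)
      nm <- transformed_name(f)
      v <- transform_value(f, records[[b$name]])
      if (anyNA(v)) stop("encoding error: '", b$name,
                         "' is missing but has no missing level")
      cols[[nm]] <- v
      factor_of[nm] <- b$name
    } else if (b$type == "cat_volume") {
      vals <- map_to_kept(categorize_volume(records[[b$name]]),
                          b$levels, b$name)
      m <- dummy_cols(vals, b$levels, paste0(b$name, "_cat"))
      for (j in colnames(m)) { cols[[j]] <- m[, j]; factor_of[j] <- b$name }
    } else if (b$type == "mi_cont") {
      f <- schema_get(schema, b$name)
      v <- records[[b$name]]
      mis <- as.numeric(is.na(v))
      tv <- transform_value(f, v)
      tv[is.na(tv)] <- 0
      if (b$has_missing) {
        nm <- paste0(b$name, "_missing_ind")
        cols[[nm]] <- mis
        factor_of[nm] <- b$name
      } else if (any(mis > 0)) {
        stop("encoding error: '", b$name, "' missing at prediction but the ",
             "training data had no missing values for it")
      }
      nm <- paste0(transformed_name(f), "_obs")
      cols[[nm]] <- (1 - mis) * tv
      factor_of[nm] <- b$name
    } else if (b$type == "combined_famhx") {
      vals <- combine_family_history(records[[b$sources[1]]],
                                     records[[b$sources[2]]])
      vals <- map_to_kept(vals, b$levels, b$name)
      m <- dummy_cols(vals, b$levels, b$name)
      for (j in colnames(m)) {
        cols[[j]] <- m[, j]
        factor_of[j] <- paste(b$sources, collapse = "+")
      }
    } else { # cat
      vals <- ifelse(is.na(records[[b$name]]), "missing",
                     as.character(records[[b$name]]))
      vals <- map_to_kept(vals, b$levels, b$name)
      m <- dummy_cols(vals, b$levels, b$name)
      for (j in colnames(m)) { cols[[j]] <- m[, j]; factor_of[j] <- b$name }
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, terms = names(cols), factor_of = factor_of)
}

encode_raw <- function(records, pattern, schema) {
  pattern <- as_pattern(pattern, schema)
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  factor_of <- c(`(Intercept)` = NA_character_)
  for (nm in pattern) {
    f <- schema_get(schema, nm)
    v <- records[[nm]]
    if (is.null(v)) stop("records lack column '", nm, "'")
    if (anyNA(v))
      stop("encoding error: '", nm,
           "' has missing values; raw coding requires complete records")
    if (f$kind == "continuous") {
      tn <- transformed_name(f)
      cols[[tn]] <- transform_value(f, v)
      factor_of[tn] <- nm
    } else {
      v <- as.character(v)
      bad <- setdiff(unique(v), f$levels)
      if (length(bad))
        stop("encoding error: unknown level '", bad[1], "' for '", nm, "'")
      for (l in f$levels[-1]) {
        tn <- paste0(nm, "_", l)
        cols[[tn]] <- as.numeric(v == l)
        factor_of[tn] <- nm
      }
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, terms = names(cols), factor_of = factor_of)
}

#' Encode records into a design matrix
#'
#' Builds the logistic-regression design matrix for a set of records under
#' one of three codings. `"raw"` uses the factors in `pattern` and requires
#' the records to be complete on it: continuous factors enter transformed
#' per the schema (PSA and prostate volume as log2; age untransformed),
#' binary/categorical factors are dummy coded against their declared
#' reference level. `"categorized"` and `"missing_indicator"` use all schema
#' factors, recoding missing values into explicit levels (or an indicator
#' plus a zero-filled value term for optional continuous factors), so no
#' record is excluded.
#'
#' Term names are deterministic: `<factor>_log2` for log2-transformed
#' continuous factors, `<factor>_<level>` for dummies, `<factor>_cat_<level>`
#' for stratified volume, `<factor>_missing_ind` / `<factor>_log2_obs` for
#' the missing-indicator blocks, and `famhx2_<level>` for the combined
#' family-history factor.
#'
#' @param records data.frame of records (see [cohort_data()]).
#' @param pattern factor subset for `coding = "raw"`; ignored by the
#'   all-data codings, which always use the full schema.
#' @param schema a [risk_schema()].
#' @param coding `"raw"`, `"categorized"` or `"missing_indicator"`.
#' @param recode_info optional recode plan built on training data; when
#'   `NULL` it is derived from `records` themselves.
#' @return list with `x` (matrix incl. intercept), `terms`, `factor_of`
#'   (term -> source factor) and, for the all-data codings, `recode_info`.
#' @export
encode_design <- function(records, pattern = NULL, schema,
                          coding = c("raw", "categorized",
                                     "missing_indicator"),
                          recode_info = NULL) {
  coding <- match.arg(coding)
  if (coding == "raw") {
    if (is.null(pattern)) stop("raw coding requires a pattern")
    return(encode_raw(records, pattern, schema))
  }
  if (is.null(recode_info))
    recode_info <- build_recode_info(records, schema, coding)
  out <- encode_with_recode(records, recode_info, schema)
  out$recode_info <- recode_info
  out
}
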