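#' Bidirectional stepwise model selection by BIC
#'
#' Starting from the model containing every candidate main effect (plus the
#' forced terms), repeatedly applies the single move -- add a main effect,
#' add an eligible two-way interaction, drop an interaction, or drop a main
#' effect together with its interactions -- that yields the largest BIC
#' decrease, stopping at a local minimum. Interaction terms obey the
#' hierarchy: they are eligible only while both parent main effects are in
#' the model. Ties are broken deterministically by term-name order.
#'
#' @param x design matrix including an intercept column, the forced terms
#'   and every candidate main-effect column.
#' @param y 0/1 outcomes.
#' @param forced term names always kept in the model (the intercept is
#'   always forced; mandatory predictors are typically forced too).
#' @param candidates main-effect term names the search may add or drop.
#' @param allow_interactions consider two-way interactions among the
#'   non-intercept terms currently in the model.
#' @param control a [logistic_control()].
#' @return list with `model` (the final `fitted_logistic`), `selected`
#'   (candidate main effects retained), `interactions` (names `a:b`),
#'   `bic` and `steps` (number of accepted moves).
#' @export
stepwise_bic <- function(x, y, forced = "(Intercept)",
                         candidates = setdiff(colnames(x), forced),
                         allow_interactions = TRUE,
                         control = logistic_control()) {
  x <- as.matrix(x)
  stopifnot("(Intercept)" %in% colnames(x))
  forced <- union("(Intercept)", forced)
  stopifnot(all(c(forced, candidates) %in% colnames(x)))
  candidates <- sort(setdiff(candidates, forced))

  int_cache <- new.env(parent = emptyenv())
  int_col <- function(key) {
    if (is.null(int_cache[[key]])) {
      ab <- strsplit(key, ":", fixed = TRUE)[[1]]
      int_cache[[key]] <- x[, ab[1]] * x[, ab[2]]
    }
    int_cache[[key]]
  }
  int_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")

  fit_cache <- new.env(parent = emptyenv())
  eval_model <- function(mains, ints) {
    sig <- paste0("m|", paste(c(sort(mains), sort(ints)), collapse = "|"))
    got <- fit_cache[[sig]]
    if (!is.null(got)) return(got)
    xm <- x[, c(forced, sort(mains)), drop = FALSE]
    if (length(ints)) {
      im <- vapply(sort(ints), int_col, numeric(nrow(x)))
      if (nrow(x) == 1L) im <- matrix(im, nrow = 1L)
      colnames(im) <- sort(ints)
      xm <- cbind(xm, im)
    }
    out <- tryCatch({
      m <- fit_logistic(xm, y, control)
      list(bic = bic(m), model = m)
    }, patternrisk_error = function(e) list(bic = Inf, model = NULL))
    fit_cache[[sig]] <- out
    out
  }

  mains <- candidates
  ints <- character(0)
  cur <- eval_model(mains, ints)
  if (is.infinite(cur$bic))
    stop("stepwise start model could not be fit (",
         "separation or insufficient data)")
  steps <- 0L
  repeat {
    moves <- list()
    add_move <- function(mains2, ints2, label)
      moves[[length(moves) + 1L]] <<- list(mains = mains2, ints = ints2,
                                           label = label)
    for (m in sort(mains))
      add_move(setdiff(mains, m),
               ints[!vapply(strsplit(ints, ":", fixed = TRUE),
                            function(p) m %in% p, logical(1))],
               paste0("-", m))
    for (i in sort(ints)) add_move(mains, setdiff(ints, i), paste0("-", i))
    for (m in setdiff(candidates, mains))
      add_move(sort(c(mains, m)), ints, paste0("+", m))
    if (allow_interactions) {
      parents <- setdiff(c(forced, mains), "(Intercept)")
      if (length(parents) >= 2) {
        pairs <- utils::combn(sort(parents), 2)
        for (k in seq_len(ncol(pairs))) {
          key <- int_key(pairs[1, k], pairs[2, k])
          if (!key %in% ints) add_move(mains, sort(c(ints, key)),
                                       paste0("+", key))
        }
      }
    }
    if (!length(moves)) break
    bics <- vapply(moves, function(mv) eval_model(mv$mains, mv$ints)$bic,
                   numeric(1))
    best <- which.min(bics)
    if (!length(best) || bics[best] >= cur$bic - 1e-8) break
    mv <- moves[[best]]
    mains <- mv$mains
    ints <- mv$ints
    cur <- eval_model(mains, ints)
    steps <- steps + 1L
    if (steps > 200L) break
  }
  list(model = cur$model, selected = sort(mains), interactions = sort(ints),
       bic = cur$bic, steps = steps)
}
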