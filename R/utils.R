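# Internal helpers: typed conditions and seeded evaluation.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("sctfidf_input_error", "sctfidf_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("sctfidf_format_error", "sctfidf_error")))
}

stop_value <- function(...) {
  stop(errorCondition(paste0(...), class = c("sctfidf_value_error", "sctfidf_error")))
}

stop_empty <- function(...) {
  stop(errorCondition(paste0(...), class = c("sctfidf_empty_result_error", "sctfidf_error")))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded package internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# logsumexp over rows of a matrix
.row_logsumexp <- function(lp) {
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

# 0-based contiguous relabeling ordered by first occurrence
.relabel <- function(labels) {
  match(labels, unique(labels)) - 1L
}
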