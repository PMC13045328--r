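#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Seeds the generator locally and restores the caller's RNG state on exit,
#' so seeded package functions never disturb global random-number state.
#' With `seed = NULL` the expression runs under the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Normalize species labels
#'
#' Exact matching after underscore/space normalization: spaces become
#' underscores and surrounding whitespace is dropped. No fuzzy matching.
#'
#' @param x Character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}

# stop with a classed condition so callers/tests can match on class
stop_canopyshift <- function(msg, class) {
  stop(structure(
    class = c(class, "canopyshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# derive a stream-specific 32-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 104729L * as.integer(stream)) %% 2147483647L
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
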