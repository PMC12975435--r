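#' Evaluate an expression under a local RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so package functions never leak randomness
#' into (or depend on) the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# population variance / sd (denominator n)
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))
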