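`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that library code never
#' clobbers a user's simulation stream. `seed = NULL` evaluates `code`
#' against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# stopifnot with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
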