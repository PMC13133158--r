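#' Derive an independent child seed from a master seed
#'
#' All randomised operations in the package draw from locally scoped RNG
#' streams keyed by `child_seed(seed, stream)`, so adding a new draw to one
#' component never perturbs the stream of another.
#'
#' @param seed Master seed (non-negative integer).
#' @param stream Stream index (non-negative integer).
#' @return An integer seed strictly below 2^31.
#' @keywords internal
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  # multiplicative hash keeps distinct (seed, stream) pairs well separated
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 69621 + 1
  as.integer(x %% 2147483647)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single positive integer", name),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

assert_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}
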