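# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so simulation functions are
#' reproducible without clobbering the user's random-number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(unique(x)) <= 2L && all(x %in% c(0, 1))
}

#' Clamp probabilities away from 0/1 for deviance computation
#' @noRd
clamp_prob <- function(p, eps = 1e-10) pmin(pmax(p, eps), 1 - eps)

#' Binomial deviance contribution (-2 log-likelihood)
#' @noRd
binomial_deviance <- function(y, p) {
  p <- clamp_prob(p)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}
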