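#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state so callers' random streams are unaffected.
#' With `seed = NULL` the code runs against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# scalar-argument validators; stop with a readable message
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", name), call. = FALSE)
  }
  invisible(x)
}

#' Complementary error function
#'
#' `erfc(z) = 2 * pnorm(-z * sqrt(2))`, exposed because the diffusion model
#' is written in terms of it.
#'
#' @param z numeric vector.
#' @return `erfc(z)`.
#' @export
erfc <- function(z) 2 * stats::pnorm(-z * sqrt(2))
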