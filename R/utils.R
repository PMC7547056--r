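#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Each output table draws from its own sub-stream so that changing the
#' parameters of one table does not perturb the draws of another.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the sub-stream.
#' @return an integer seed < 2^31.
#' @keywords internal
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded from `sub_seed(seed, tag)` and restores
#' the caller's RNG state afterwards, so library code never clobbers a
#' user's random stream.
#'
#' @keywords internal
with_subseed <- function(seed, tag, code) {
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
  set.seed(sub_seed(seed, tag))
  force(code)
}

# z-score a vector; constant vectors map to 0 rather than NaN
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
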