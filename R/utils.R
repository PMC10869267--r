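# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered running mean with shrunken edge windows
#'
#' Smooths a numeric vector with a centered window of `k` points. For even
#' `k` the window extends one point further to the right than to the left.
#' At the vector edges the window is clipped, so edge values are means over
#' fewer points rather than being dropped or padded.
#'
#' @param x numeric vector.
#' @param k window size in points (>= 1).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
running_mean <- function(x, k) {
  stopifnot(k >= 1)
  n <- length(x)
  if (n == 0L || k == 1L) return(x)
  left <- floor((k - 1) / 2)
  right <- k - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Flag-bit accessors for SAM FLAG fields.
sam_is_paired <- function(flag) bitwAnd(flag, 0x1L) > 0L
sam_is_proper_pair <- function(flag) bitwAnd(flag, 0x2L) > 0L
sam_is_reverse <- function(flag) bitwAnd(flag, 0x10L) > 0L
sam_is_read1 <- function(flag) bitwAnd(flag, 0x40L) > 0L
sam_is_read2 <- function(flag) bitwAnd(flag, 0x80L) > 0L
sam_is_dup <- function(flag) bitwAnd(flag, 0x400L) > 0L

#' Seeded evaluation
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulators are deterministic without clobbering the
#' session RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
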