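#' Seeded uniform draws
#'
#' Reproducible uniform samples used as the stochastic inputs of the
#' unequal-respiration scenario (the analysis consumes parameters, not
#' measurements). Identical `(n, low, high, seed)` always yield the
#' identical sequence; the draw is isolated from, and does not disturb, the
#' caller's RNG state.
#'
#' @param n Number of draws, positive integer.
#' @param low,high Interval bounds, `low < high`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n` in `[low, high)`.
#' @export
#' @examples
#' uniform_draws(5, 0, 0.02, seed = 1)
uniform_draws <- function(n, low, high, seed) {
  stopifnot(
    is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
    is.numeric(low), is.numeric(high), low < high,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  withr::with_seed(as.integer(seed), stats::runif(n, min = low, max = high))
}

#' Inclusive arithmetic grid
#'
#' Index-based construction `start + k * step` (never repeated addition), so
#' every grid point is exactly reproducible across platforms and the
#' endpoint is included whenever `(stop - start)` is an integer number of
#' steps to within 1e-12 relative.
#'
#' @param start,stop Grid limits, `stop >= start`.
#' @param step Positive increment. Ignored when `start == stop`.
#' @return Numeric vector `start, start + step, ..., <= stop`.
#' @export
#' @examples
#' length(make_grid(0, 0.02, 0.0005)) # 41 respiration rates
make_grid <- function(start, stop, step) {
  stopifnot(
    is.numeric(start), is.numeric(stop), is.numeric(step),
    length(start) == 1L, length(stop) == 1L, length(step) == 1L,
    is.finite(start), is.finite(stop), stop >= start
  )
  if (stop == start) {
    return(start)
  }
  if (!is.finite(step) || step <= 0) {
    abort("`step` must be strictly positive")
  }
  n <- floor((stop - start) / step + 1e-9)
  start + step * (0:n)
}

# Deterministic per-scenario substream: scenarios draw from independent,
# reproducible streams derived from one top-level seed. Kept below 2^31 - 1.
substream_seed <- function(seed, scenario) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  offset <- sum(utf8ToInt(as.character(scenario)) * seq_along(
    utf8ToInt(as.character(scenario))
  ))
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}
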