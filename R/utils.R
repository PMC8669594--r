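# Shared helpers: half-open interval arithmetic and seeded evaluation.

#' Number of samples in a half-open interval
#'
#' The package uses the half-open convention everywhere: the interval
#' `[a, b)` sampled at `rate` Hz contains `round((b - a) * rate)` samples at
#' times `a, a + 1/rate, ...`. This makes the 5.5-s temporal region of
#' interest at 16 Hz contain exactly 88 samples.
#'
#' @param a,b interval bounds in seconds (`a < b`)
#' @param rate sampling rate in Hz
#' @return integer sample count
#' @export
n_samples_ho <- function(a, b, rate) {
  stopifnot(is.numeric(a), is.numeric(b), b > a, rate > 0)
  as.integer(round((b - a) * rate))
}

#' Time axis for a half-open interval
#'
#' @inheritParams n_samples_ho
#' @return numeric vector of sample times `a + (0:(n-1))/rate`
#' @export
time_axis_ho <- function(a, b, rate) {
  n <- n_samples_ho(a, b, rate)
  a + (seq_len(n) - 1) / rate
}

# Evaluate fn() under a given RNG seed, restoring the caller's RNG state.
run_seeded <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# Derive a stream of child seeds (< 2^31) from a master seed.
child_seeds <- function(seed, n) {
  run_seeded(seed, function() sample.int(.Machine$integer.max - 1L, n))
}

# index of time t on a grid starting at t0 with given rate (1-based, exact
# up to rounding of half a sample)
grid_index <- function(t, t0, rate) as.integer(round((t - t0) * rate)) + 1L
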