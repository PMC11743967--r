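# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Largest-remainder apportionment of n items to proportions
#'
#' Returns integer counts summing to `n` that are as close as possible to
#' `n * probs`, assigning leftover units to the largest fractional remainders
#' (ties resolved toward the earlier category, so the result is deterministic).
#'
#' @param n total count to apportion.
#' @param probs non-negative proportions; normalised internally.
#' @return integer vector of counts, same length as `probs`, summing to `n`.
#' @keywords internal
largest_remainder <- function(n, probs) {
  stopifnot(n >= 0, all(probs >= 0), sum(probs) > 0)
  x <- n * probs / sum(probs)
  base <- floor(x)
  short <- n - sum(base)
  if (short > 0) {
    rem <- x - base
    idx <- order(-rem, seq_along(rem))[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Draw n values whose marginal histogram is fixed by largest-remainder
# rounding of the target proportions; the seed only shuffles which unit
# receives which value. Used for reported cohort-level marginals (gender,
# life-satisfaction) that the simulation must reproduce at any seed.
draw_calibrated <- function(n, probs, values) {
  stopifnot(length(probs) == length(values))
  counts <- largest_remainder(n, probs)
  pool <- rep(values, times = counts)
  pool[sample.int(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
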