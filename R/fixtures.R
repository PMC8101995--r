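## Synthetic generators and brute-force oracles used by the test suite and
## the documentation examples.

#' Pair of independent renewal spike trains
#'
#' Two independent trains with uniform IPI jitter around \code{1000/rate}
#' ms, starting at a uniform phase within one IPI, rounded to the 1-ms
#' grid.  Intended for analytic-expectation checks: for independent
#' trains the expected central-bin coincidence probability of
#' \code{\link{cross_intervals}} is about \code{rate2/1000}.
#'
#' Uses the current RNG state; seed the session for reproducibility.
#'
#' @param rate1,rate2 mean firing rates in Hz.
#' @param duration_ms train duration (0 gives empty trains).
#' @param jitter uniform IPI half-width in ms.
#' @return List with integer pulse-time vectors \code{train1} and
#'   \code{train2}.
#' @export
make_renewal_pair <- function(rate1, rate2, duration_ms, jitter = 4) {
  if (rate1 <= 0 || rate2 <= 0) stop("rates must be positive")
  one <- function(rate) {
    if (duration_ms <= 0) return(integer(0))
    ipi <- 1000 / rate
    if (ipi - jitter <= 1) stop("jitter too wide for the rate")
    t <- stats::runif(1, 0, ipi)
    times <- numeric(ceiling(duration_ms / (ipi - jitter)) + 16)
    n <- 0L
    while (t < duration_ms) {
      n <- n + 1L
      times[n] <- t
      t <- t + stats::runif(1, ipi - jitter, ipi + jitter)
    }
    if (n == 0L) return(integer(0))
    pt <- as.integer(round(times[seq_len(n)]))
    for (i in seq_len(n)[-1]) if (pt[i] <= pt[i - 1]) pt[i] <- pt[i - 1] + 1L
    pt[pt < duration_ms]
  }
  list(train1 = one(rate1), train2 = one(rate2))
}

#' Brute-force cross-interval oracle
#'
#' Exhaustive O(n^2) nearest-neighbour search with the same tie rule as
#' \code{\link{cross_intervals}} (equidistant partner pulses resolve to
#' the earlier one).  Intended as an independent oracle on small trains.
#'
#' @param reference,partner integer pulse times in ms.
#' @param window half-open analysis window in ms.
#' @return A \code{cross_intervals} object.
#' @export
brute_force_ci <- function(reference, partner, window = c(2000, 4000)) {
  r <- reference[reference >= window[1] & reference < window[2]]
  p <- partner[partner >= window[1] & partner < window[2]]
  if (!length(r)) stop("reference train has no pulse in the window")
  if (!length(p)) {
    return(structure(list(values = integer(0), n_reference = length(r)),
                     class = "cross_intervals"))
  }
  vals <- vapply(r, function(t1) {
    d <- abs(t1 - p)
    best <- p[which(d == min(d))]   # earlier partner on ties
    as.integer(t1 - min(best))
  }, integer(1))
  structure(list(values = vals, n_reference = length(r)),
            class = "cross_intervals")
}
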