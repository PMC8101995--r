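## Force statistics, spectral analysis and the window-trend correlations.

.window_samples <- function(trace, window) {
  if (window[2] > length(trace) || window[1] < 0 || window[2] <= window[1]) {
    stop("analysis window outside the trace")
  }
  trace[(window[1] + 1L):window[2]]
}

#' Basic force statistics over the steady state
#'
#' Over the \code{n} samples of the window: the mean force, the maximum,
#' the min-max range, and the root-mean-square of the deviation from the
#' mean, \eqn{rmsF = \sqrt{\sum_i (F_i - meanF)^2 / n}} (a population
#' standard deviation, so a constant trace has \code{rmsF = 0}).
#'
#' @param trace a force trace in mN at 1 kHz.
#' @param window half-open analysis window in ms.
#' @return Named list with \code{meanF}, \code{maxF}, \code{rangeF},
#'   \code{rmsF} (mN).
#' @export
force_stats <- function(trace, window = c(2000, 4000)) {
  x <- .window_samples(trace, window)
  m <- mean(x)
  list(meanF = m, maxF = max(x), rangeF = max(x) - min(x),
       rmsF = sqrt(mean((x - m)^2)))
}

#' Variance accounted for between two force traces
#'
#' \deqn{VAF = 100 (1 - var(FS - FNS) / var(FNS))\,[\%],} with both
#' variances taken about their own means over the window.  Equal traces
#' give 100%; the index goes negative when the variance of the difference
#' exceeds the variance of the reference, as happens under strong
#' synchronization.
#'
#' @param fs_trace the (synchronized) trace under test.
#' @param fns_trace the non-synchronized reference trace.
#' @param window half-open analysis window in ms.
#' @return Percent (may be negative); \code{NA} when the reference is
#'   constant over the window.
#' @export
vaf <- function(fs_trace, fns_trace, window = c(2000, 4000)) {
  s <- .window_samples(fs_trace, window)
  r <- .window_samples(fns_trace, window)
  d <- s - r
  ssr <- sum((r - mean(r))^2)
  if (ssr == 0) return(NA_real_)
  100 * (1 - sum((d - mean(d))^2) / ssr)
}

#' Power spectrum of the force oscillation
#'
#' The window is mean-subtracted (the oscillatory component is analyzed,
#' not the DC force level), left untapered, zero-padded to \code{nf}
#' points and Fourier transformed; the one-sided magnitude-squared
#' spectrum is returned over bins \code{1..nf/2}, i.e. excluding DC, with
#' a frequency resolution of \code{1000/nf} Hz.
#'
#' @param trace a force trace in mN at 1 kHz.
#' @param window half-open analysis window in ms.
#' @param nf FFT length (>= window length).
#' @return A \code{force_spectrum}: data frame with columns \code{freq_hz}
#'   and \code{psd}.
#' @export
force_psd <- function(trace, window = c(2000, 4000), nf = 2048) {
  x <- .window_samples(trace, window)
  if (nf < length(x)) stop("nf must be at least the window length")
  x <- c(x - mean(x), numeric(nf - length(x)))
  X <- stats::fft(x)
  k <- seq_len(nf / 2)
  structure(data.frame(freq_hz = k * 1000 / nf, psd = Mod(X[k + 1])^2),
            class = c("force_spectrum", "data.frame"))
}

#' Mean spectral frequency
#'
#' PSD-weighted average frequency,
#' \eqn{meanfreq = \sum_i f_i PSD_i / \sum_i PSD_i}, over the one-sided
#' DC-excluded spectrum.
#'
#' @param spec a \code{force_spectrum}.
#' @return Frequency in Hz; \code{NA} for an all-zero spectrum.
#' @export
mean_freq <- function(spec) {
  tot <- sum(spec$psd)
  if (tot == 0) return(NA_real_)
  sum(spec$freq_hz * spec$psd) / tot
}

#' Correlation of force-parameter trends with the synchronization trend
#'
#' Given the values of the synchronization index and of force parameters
#' at the non-synchronized baseline and at each synchronization window
#' (e.g. dt = 0, 2, 4, 6 ms), computes the Pearson correlation between the
#' synchronization-index curve and each parameter curve.
#'
#' @param curves data frame with a \code{cisi} column and one column per
#'   force parameter, one row per window setting (including the baseline).
#' @return Named numeric vector of correlations; \code{NA} for a constant
#'   curve.
#' @export
trend_correlation <- function(curves) {
  if (!"cisi" %in% names(curves)) stop("curves must contain a 'cisi' column")
  params <- setdiff(names(curves), c("cisi", "window", "method", "group"))
  out <- vapply(params, function(p) {
    y <- curves[[p]]
    if (stats::sd(y) == 0 || stats::sd(curves$cisi) == 0) return(NA_real_)
    stats::cor(curves$cisi, y)
  }, numeric(1))
  names(out) <- params
  out
}
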