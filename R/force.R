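## Twitch model calibrated to the pool table, tetanic summation with
## saturation, and group/muscle force traces.

#' Evaluate a fitted twitch waveform
#'
#' The twitch of one unit is modelled by the gamma-type analytic form
#' \deqn{f(t) = F_{max} (t/T_c)^m e^{m (1 - t/T_c)}, \quad 0 < t \le T_{tw},}
#' which peaks at exactly \eqn{F_{max}} at \eqn{t = T_c} for any shape
#' exponent \eqn{m > 0}, and is truncated to zero beyond the twitch
#' duration \eqn{T_{tw}}.
#'
#' @param params a \code{twitch_params} object from \code{\link{fit_twitch}}.
#' @param t times since the pulse, ms (vectorized).
#' @return Force in mN.
#' @export
twitch_waveform <- function(params, t) {
  ifelse(t <= 0 | t > params$Ttw, 0,
         params$Fmax * (t / params$Tc)^params$m *
           exp(params$m * (1 - t / params$Tc)))
}

## time after the peak at which the waveform decays to half of Fmax
.half_decay <- function(m, Tc) {
  f <- function(t) (t / Tc)^m * exp(m * (1 - t / Tc)) - 0.5
  hi <- 2 * Tc
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(Tc, hi), tol = 1e-9)$root - Tc
}

#' Fit the twitch shape of one unit
#'
#' Anchors the waveform of \code{\link{twitch_waveform}} to the unit's
#' measured parameters: the peak equals \eqn{F_{max}} at \eqn{t = T_c} by
#' construction, and the shape exponent \eqn{m} is found by bisection on
#' \eqn{[0.05, 8]} so that the time from the peak down to half the peak
#' force matches the measured half-relaxation time \eqn{T_{hr}}.  The
#' waveform is truncated at the twitch duration \eqn{T_{tw}}.
#'
#' @param mu one row of a \code{mu_pool}.
#' @param tol maximum allowed residual between the fitted and the measured
#'   half-relaxation time, ms.
#' @return A \code{twitch_params} object: list with \code{index},
#'   \code{label}, \code{m}, \code{Tc}, \code{Fmax}, \code{Ttw},
#'   \code{Thr_fitted} and \code{Thr_residual}.
#' @export
#' @examples
#' pool <- load_pool()
#' fit_twitch(pool[pool$label == "FR1", ])$m  # about 0.77
fit_twitch <- function(mu, tol = 0.5) {
  lo <- 0.05
  hi <- 8
  ## half-decay time is strictly decreasing in m
  g <- function(m) .half_decay(m, mu$Tc) - mu$Thr
  if (g(lo) < 0 || g(hi) > 0) {
    stop(sprintf("unit %s: no shape exponent in [%g, %g] reaches Thr = %g ms",
                 mu$label, lo, hi, mu$Thr))
  }
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  m <- (lo + hi) / 2
  thr_fit <- .half_decay(m, mu$Tc)
  if (abs(thr_fit - mu$Thr) > tol) {
    stop(sprintf("unit %s: twitch fit residual %.3f ms exceeds %.1f ms",
                 mu$label, thr_fit - mu$Thr, tol))
  }
  structure(list(index = mu$index, label = mu$label, m = m,
                 Tc = mu$Tc, Fmax = mu$Fmax, Ttw = mu$Ttw,
                 Thr_fitted = thr_fit, Thr_residual = thr_fit - mu$Thr),
            class = "twitch_params")
}

#' Fit the twitches of a whole pool
#'
#' @param pool a \code{mu_pool}.
#' @param tol passed to \code{\link{fit_twitch}}.
#' @return Named list of \code{twitch_params}, one per unit.
#' @export
fit_twitch_pool <- function(pool, tol = 0.5) {
  out <- lapply(seq_len(nrow(pool)), function(i) fit_twitch(pool[i, ], tol))
  names(out) <- pool$label
  out
}

## twitch kernel sampled on the 1-ms grid (t = 1..floor(Ttw))
.twitch_kernel <- function(params) {
  twitch_waveform(params, seq_len(floor(params$Ttw)))
}

#' Force trace of one unit
#'
#' Linear superposition of one twitch per pulse,
#' \eqn{L(t) = \sum_k f(t - t_k)}, optionally passed through the smooth
#' per-unit saturation \eqn{F(t) = F_{mftf} \tanh(L(t)/F_{mftf})} which
#' caps the fused-tetanus force at \eqn{F_{mftf}} while leaving a single
#' isolated twitch almost untouched (the twitch-to-tetanus force ratios of
#' the pool make the compression of one twitch at most a few percent).
#'
#' @param train integer pulse times in ms.
#' @param params the unit's \code{twitch_params}.
#' @param mu the matching \code{mu_pool} row (supplies \code{Fmftf}).
#' @param saturate apply the tanh saturation (default) or keep the purely
#'   linear summation.
#' @param duration_ms trace length.
#' @return Numeric force trace in mN, sampled at 1 kHz (element \code{i} is
#'   the force at time \code{i - 1} ms).
#' @export
mu_force <- function(train, params, mu, saturate = TRUE, duration_ms = 4000) {
  L <- numeric(duration_ms)
  train <- train[train >= 0 & train < duration_ms]
  if (length(train)) {
    spk <- numeric(duration_ms)
    spk[train + 1L] <- spk[train + 1L] + 1
    ker <- c(0, .twitch_kernel(params))
    conv <- stats::convolve(spk, rev(ker), type = "open")
    L <- pmax(conv[seq_len(duration_ms)], 0)
    L[L < 1e-9] <- 0      # FFT round-off residue
  }
  if (saturate) mu$Fmftf * tanh(L / mu$Fmftf) else L
}

#' Force traces of the pool, its type groups and the whole muscle
#'
#' @param firings a \code{firing_set}.
#' @param pool the matching \code{mu_pool}.
#' @param twitches the list from \code{\link{fit_twitch_pool}}.
#' @param saturate,duration_ms passed to \code{\link{mu_force}};
#'   \code{duration_ms} defaults to the duration of the firing set.
#' @return A \code{force_set}: list with \code{mu} (units x samples
#'   matrix), \code{group} (samples x 3 matrix, columns S/FR/FF) and
#'   \code{muscle} (vector), each in mN at 1 kHz; group and muscle traces
#'   are exact sample-wise sums of their unit traces.
#' @export
group_forces <- function(firings, pool, twitches, saturate = TRUE,
                         duration_ms = firings$duration_ms) {
  Fm <- t(vapply(seq_len(nrow(pool)), function(i) {
    mu_force(firings$trains[[pool$label[i]]], twitches[[pool$label[i]]],
             pool[i, ], saturate, duration_ms)
  }, numeric(duration_ms)))
  rownames(Fm) <- pool$label
  grp <- vapply(.mu_types, function(ty) {
    colSums(Fm[pool$type == ty, , drop = FALSE])
  }, numeric(duration_ms))
  structure(list(mu = Fm, group = grp, muscle = rowSums(grp),
                 provenance = firings$provenance, seed = firings$seed),
            class = "force_set")
}

#' Export group and muscle force traces as CSV
#'
#' Wide layout with columns \code{time_ms, muscle, S, FR, FF} (mN).
#'
#' @param forces a \code{force_set}.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_forces <- function(forces, path) {
  df <- data.frame(time_ms = seq_along(forces$muscle) - 1L,
                   muscle = forces$muscle,
                   S = forces$group[, "S"],
                   FR = forces$group[, "FR"],
                   FF = forces$group[, "FF"])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
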