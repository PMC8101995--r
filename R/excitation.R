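## Excitation drive, size-principle recruitment and the rate law.

#' Excitation signal with logarithmic ramps
#'
#' Builds the common excitatory drive sampled at 1 kHz: a smooth logarithmic
#' rise over \code{rise_ms}, a constant plateau at \code{level} over
#' \code{plateau_ms}, and a falling phase that is the time-mirrored rise.
#' The rising part is \eqn{e(t) = level \cdot \log(1 + s t / rise) /
#' \log(1 + s)} with shape parameter \eqn{s}; only the plateau (where every
#' unit is active) is analyzed by the synchronization and force metrics, so
#' the ramp shape affects recruitment timing but no steady-state statistic.
#'
#' @param level plateau drive, percent of maximum (0, 100].
#' @param rise_ms,plateau_ms,fall_ms phase durations in ms.
#' @param shape positive curvature of the logarithmic ramp.
#' @param delay_ms silent lead-in at zero drive before the rise, ms.  The
#'   simulation pipeline uses a 1000-ms lead-in so that the plateau covers
#'   exactly the 2000-4000 ms analysis window.
#' @return An \code{excitation_trace}: list with \code{values} (one sample
#'   per ms, percent) and \code{duration_ms}.
#' @export
#' @examples
#' e <- excitation_signal()
#' e$values[1501]  # mid-plateau: 100
excitation_signal <- function(level = 100, rise_ms = 1000, plateau_ms = 2000,
                              fall_ms = 1000, shape = 9, delay_ms = 0) {
  if (!(level > 0 && level <= 100)) stop("level must be in (0, 100]")
  if (min(rise_ms, plateau_ms, fall_ms) <= 0) stop("phase durations must be positive")
  if (shape <= 0) stop("shape must be positive")
  if (delay_ms < 0) stop("delay_ms must be nonnegative")
  total <- delay_ms + rise_ms + plateau_ms + fall_ms
  t <- seq_len(total) - 1
  v <- numeric(total)
  ris <- t >= delay_ms & t < delay_ms + rise_ms
  v[ris] <- level * log1p(shape * (t[ris] - delay_ms) / rise_ms) / log1p(shape)
  v[t >= delay_ms + rise_ms & t < delay_ms + rise_ms + plateau_ms] <- level
  fal <- t >= delay_ms + rise_ms + plateau_ms
  v[fal] <- level * log1p(shape * (total - t[fal]) / fall_ms) / log1p(shape)
  structure(list(values = v, duration_ms = total,
                 level = level, shape = shape),
            class = "excitation_trace")
}

#' Size-principle recruitment plan
#'
#' Orders the pool for recruitment by type block (S, then FR, then FF), and
#' within each block by increasing maximum twitch force, i.e. from the
#' weakest to the strongest unit; for the builtin pool this is simply the
#' table order 1..57.  Recruitment thresholds are evenly spaced over
#' \code{(0, span]} percent of drive, so with the default span all units are
#' recruited well before the drive reaches its plateau.
#'
#' @param pool a \code{mu_pool}.
#' @param span percent of drive at which the last unit is recruited, in
#'   (0, 100).
#' @return A \code{recruitment_plan}: list with \code{order} (unit indices
#'   in recruitment sequence) and \code{threshold} (percent, named by unit
#'   index, in pool order).
#' @export
recruitment_plan <- function(pool, span = 90) {
  if (!(span > 0 && span < 100)) stop("span must be in (0, 100)")
  type_rank <- match(pool$type, .mu_types)
  ord <- order(type_rank, pool$Fmax, pool$index)
  n <- nrow(pool)
  thr <- numeric(n)
  thr[ord] <- span * seq_len(n) / n
  names(thr) <- pool$index
  structure(list(order = pool$index[ord], threshold = thr, span = span),
            class = "recruitment_plan")
}

#' Instantaneous firing rate of one unit
#'
#' Rate law mapping drive to firing rate: zero below the recruitment
#' threshold, the unit's minimum rhythmic rate at threshold, then linear in
#' drive up to a maximal steady-state rate at 100% drive.  By default the
#' rate at full drive is the unit's mean rhythmic rate \code{meanfr}, so the
#' steady-state inter-pulse intervals are centred on \code{1000/meanfr};
#' \code{rate_at_max = "maxfr"} instead maps full drive to the unit's
#' maximum rhythmic rate.
#'
#' @param mu one row of a \code{mu_pool}.
#' @param drive percent of maximal drive (vectorized).
#' @param threshold recruitment threshold, percent.
#' @param rate_at_max which Table column the rate reaches at 100% drive.
#' @return Firing rate(s) in Hz; 0 below threshold.
#' @export
#' @examples
#' pool <- load_pool()
#' instantaneous_rate(pool[1, ], 100, 10)  # meanfr of S1
instantaneous_rate <- function(mu, drive, threshold,
                               rate_at_max = c("meanfr", "maxfr")) {
  rate_at_max <- match.arg(rate_at_max)
  top <- mu[[rate_at_max]]
  r <- mu$minfr + (top - mu$minfr) * (drive - threshold) / (100 - threshold)
  r <- pmin(r, top)
  ifelse(drive < threshold, 0, r)
}
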