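## Stochastic spike-train generation and binary representations.

## Deterministic per-unit substream: adding or removing units never
## perturbs the trains of the others.
.substream_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 100003 + index * 7919) %% 2147483647)
}

#' Generate one stochastic spike train
#'
#' Renewal-type pulse generator on a 1-ms grid.  The first pulse is placed
#' at the first supra-threshold time plus a uniform phase within one
#' inter-pulse interval (IPI); every subsequent IPI is drawn uniformly from
#' \code{1000/rate +/- jitter} ms, where \code{rate} is the instantaneous
#' rate at the previous pulse time.  Pulse times are accumulated in
#' continuous time, then rounded to the nearest ms; a rounding collision
#' pushes the later pulse 1 ms forward so the pulse count is preserved.
#' At full drive the rate is the unit's mean rhythmic rate, so steady-state
#' IPIs are uniform on \code{[1000/meanfr - jitter, 1000/meanfr + jitter]}.
#'
#' Uses the current RNG state; seed the session (or use
#' \code{\link{generate_pool_firings}}) for reproducibility.
#'
#' @param mu one row of a \code{mu_pool}.
#' @param excitation an \code{excitation_trace}.
#' @param threshold recruitment threshold of this unit, percent.
#' @param jitter half-width of the uniform IPI jitter, ms (>= 0).
#' @param rate_at_max see \code{\link{instantaneous_rate}}.
#' @return Integer vector of strictly increasing pulse times in ms, within
#'   \code{[0, duration)}.
#' @export
generate_train <- function(mu, excitation, threshold, jitter = 4,
                           rate_at_max = c("meanfr", "maxfr")) {
  rate_at_max <- match.arg(rate_at_max)
  if (jitter < 0) stop("jitter must be nonnegative")
  top <- mu[[rate_at_max]]
  if (1000 / top - jitter <= 1) {
    stop(sprintf("unit %s: jitter %g too wide for its rate (%g Hz)",
                 mu$label, jitter, top))
  }
  ev <- excitation$values
  duration <- excitation$duration_ms
  supra <- which(ev >= threshold)
  if (!length(supra)) return(integer(0))
  t0 <- supra[1] - 1
  drive_at <- function(t) ev[[min(duration, floor(t) + 1)]]
  rate <- instantaneous_rate(mu, drive_at(t0), threshold, rate_at_max)
  if (rate <= 0) return(integer(0))
  t <- t0 + stats::runif(1, 0, 1000 / rate)
  times <- numeric(ceiling(duration * top / 1000) + 16)
  n <- 0L
  while (t < duration) {
    n <- n + 1L
    times[n] <- t
    rate <- instantaneous_rate(mu, drive_at(t), threshold, rate_at_max)
    if (rate <= 0) break
    t <- t + stats::runif(1, 1000 / rate - jitter, 1000 / rate + jitter)
  }
  if (n == 0L) return(integer(0))
  pt <- as.integer(round(times[seq_len(n)]))
  for (i in seq_len(n)[-1]) if (pt[i] <= pt[i - 1]) pt[i] <- pt[i - 1] + 1L
  pt[pt < duration]
}

#' Generate the firing patterns of a whole pool
#'
#' One train per unit, each drawn from an independent substream derived from
#' \code{(seed, unit index)}: the same seed reproduces the whole firing set
#' bit for bit.
#'
#' @param pool a \code{mu_pool}.
#' @param excitation an \code{excitation_trace}.
#' @param plan a \code{recruitment_plan} for the pool.
#' @param seed integer master seed.
#' @param jitter,rate_at_max passed to \code{\link{generate_train}}.
#' @return A \code{firing_set}: list with \code{trains} (named by unit
#'   label), \code{seed}, \code{duration_ms} and a \code{provenance} tag
#'   (\code{"NS"} for the non-synchronized model).
#' @export
#' @examples
#' pool <- load_pool()
#' fs <- generate_pool_firings(pool, excitation_signal(), recruitment_plan(pool), seed = 1)
#' lengths(fs$trains)[1:3]
generate_pool_firings <- function(pool, excitation, plan, seed, jitter = 4,
                                  rate_at_max = c("meanfr", "maxfr")) {
  rate_at_max <- match.arg(rate_at_max)
  trains <- vector("list", nrow(pool))
  names(trains) <- pool$label
  for (i in seq_len(nrow(pool))) {
    set.seed(.substream_seed(seed, pool$index[i]))
    trains[[i]] <- generate_train(pool[i, ], excitation,
                                  plan$threshold[[as.character(pool$index[i])]],
                                  jitter = jitter, rate_at_max = rate_at_max)
  }
  structure(list(trains = trains, seed = seed,
                 duration_ms = excitation$duration_ms,
                 provenance = "NS"),
            class = "firing_set")
}

#' Binarize a spike train over the steady-state window
#'
#' Represents the train as a binary series with a 1-ms sampling period over
#' \code{[window[1], window[2])}: sample \code{i} is 1 iff a pulse occurs at
#' time \code{window[1] + i - 1}; the pulse-active state lasts one sample.
#'
#' @param train integer pulse times in ms.
#' @param window half-open analysis window in ms.
#' @return Integer 0/1 vector of length \code{diff(window)}.
#' @export
binarize <- function(train, window = c(2000, 4000)) {
  v <- integer(window[2] - window[1])
  sel <- train[train >= window[1] & train < window[2]]
  v[sel - window[1] + 1L] <- 1L
  v
}

## binary matrix (units x samples) for a firing set
.binarize_set <- function(firings, window = c(2000, 4000)) {
  t(vapply(firings$trains, binarize, integer(window[2] - window[1]),
           window = window))
}

#' Normalized inter-pulse-interval histogram
#'
#' @param train integer pulse times in ms.
#' @param window half-open analysis window in ms.
#' @return Data frame with columns \code{ipi_ms} and \code{prob} (1-ms bins,
#'   probabilities summing to 1), or zero rows when the window holds fewer
#'   than two pulses.
#' @export
ipi_histogram <- function(train, window = c(2000, 4000)) {
  p <- train[train >= window[1] & train < window[2]]
  if (length(p) < 2) {
    return(data.frame(ipi_ms = integer(0), prob = numeric(0)))
  }
  tab <- table(diff(p))
  data.frame(ipi_ms = as.integer(names(tab)),
             prob = as.numeric(tab) / sum(tab))
}

#' Write / read firing patterns as CSV
#'
#' Long layout with one row per pulse and columns
#' \code{mu_index,label,pulse_time_ms}, so externally produced firing tables
#' in the same layout can be injected into the metric functions.
#'
#' @param firings a \code{firing_set}.
#' @param pool the matching \code{mu_pool}.
#' @param path CSV file path.
#' @return \code{write_firings}: \code{path} invisibly.
#' @export
write_firings <- function(firings, pool, path) {
  n <- lengths(firings$trains)
  df <- data.frame(mu_index = rep(pool$index, n),
                   label = rep(pool$label, n),
                   pulse_time_ms = unlist(firings$trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_firings
#' @param duration_ms nominal duration of the read firing set, ms.
#' @return \code{read_firings}: a \code{firing_set} (provenance
#'   \code{"external"}).
#' @export
read_firings <- function(path, pool, duration_ms = 4000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mu_index", "label", "pulse_time_ms")
  if (!all(need %in% names(df))) {
    stop("firing file must have columns ", paste(need, collapse = ", "))
  }
  trains <- lapply(pool$index, function(i) {
    sort(as.integer(df$pulse_time_ms[df$mu_index == i]))
  })
  names(trains) <- pool$label
  structure(list(trains = trains, seed = NA_integer_,
                 duration_ms = duration_ms, provenance = "external"),
            class = "firing_set")
}
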