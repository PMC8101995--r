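## Orchestration: single scenarios and the full method x window grid.

#' Scenario configuration
#'
#' Collects every tunable of the simulation pipeline.  \code{method = 0} is
#' the non-synchronized (NS) model; the window is ignored in that case.
#'
#' @param method 0 (NS) or a synchronization method 1-4.
#' @param window synchronization half-window dt in ms.
#' @param seed master seed.
#' @param level,shape,delay_ms,rise_ms,plateau_ms,fall_ms excitation
#'   settings, see \code{\link{excitation_signal}}; with the defaults the
#'   drive is at its plateau over exactly the 2000-4000 ms analysis window.
#' @param span recruitment span, see \code{\link{recruitment_plan}}.
#' @param jitter IPI jitter half-width in ms.
#' @param rate_at_max see \code{\link{instantaneous_rate}}.
#' @param saturate apply the per-unit force saturation.
#' @return A \code{scenario_config} list.
#' @export
scenario_config <- function(method = 0, window = 4, seed = 1,
                            level = 100, shape = 9, delay_ms = 1000,
                            rise_ms = 1000, plateau_ms = 2000,
                            fall_ms = 1000, span = 90,
                            jitter = 4, rate_at_max = c("meanfr", "maxfr"),
                            saturate = TRUE) {
  if (!(length(method) == 1 && method %in% 0:4)) stop("method must be 0..4")
  structure(list(method = method, window = window, seed = seed,
                 level = level, shape = shape, delay_ms = delay_ms,
                 rise_ms = rise_ms, plateau_ms = plateau_ms,
                 fall_ms = fall_ms, span = span,
                 jitter = jitter, rate_at_max = match.arg(rate_at_max),
                 saturate = saturate),
            class = "scenario_config")
}

.steady_window <- function(config) {
  start <- config$delay_ms + config$rise_ms
  c(start, start + config$plateau_ms)
}

#' Run one simulation scenario
#'
#' Full pipeline for one configuration: excitation and recruitment,
#' stochastic NS firing, optional synchronization, synchronization summary,
#' per-group force traces and the six force statistics.  VAF is computed
#' against the NS forces of the same seed (100% for the NS scenario
#' itself).
#'
#' @param config a \code{scenario_config}.
#' @param pool a \code{mu_pool}.
#' @param twitches optional precomputed \code{\link{fit_twitch_pool}} list.
#' @param ns_ref optional \code{scenario_result} of the NS scenario with
#'   the same seed, to reuse its firings and forces.
#' @param with_forces compute force traces and statistics (set to
#'   \code{FALSE} when only synchronization indices are needed).
#' @return A \code{scenario_result}: list with \code{config},
#'   \code{firings}, \code{sync} (a \code{sync_summary}), and when
#'   requested \code{forces} plus \code{stats}, a data frame with one row
#'   per group (S, FR, FF, muscle) and columns \code{meanF}, \code{rmsF},
#'   \code{rangeF}, \code{maxF}, \code{meanfreq}, \code{vaf}.
#' @export
run_scenario <- function(config, pool = load_pool(), twitches = NULL,
                         ns_ref = NULL, with_forces = TRUE) {
  window <- .steady_window(config)
  if (!is.null(ns_ref)) {
    stopifnot(ns_ref$config$seed == config$seed)
    ns_fir <- ns_ref$firings
  } else {
    exc <- excitation_signal(config$level, config$rise_ms, config$plateau_ms,
                             config$fall_ms, config$shape, config$delay_ms)
    plan <- recruitment_plan(pool, config$span)
    ns_fir <- generate_pool_firings(pool, exc, plan, config$seed,
                                    jitter = config$jitter,
                                    rate_at_max = config$rate_at_max)
  }
  fir <- ns_fir
  if (config$method > 0) {
    sched <- schedule_for_method(config$method, pool)
    fir <- apply_method(ns_fir, sched, config$window, pool, protect = window)
  }
  sync <- summarize_sync(fir, pool, window)
  res <- list(config = config, firings = fir, sync = sync)
  if (with_forces) {
    if (is.null(twitches)) twitches <- fit_twitch_pool(pool)
    forces <- group_forces(fir, pool, twitches, saturate = config$saturate)
    ns_forces <- if (config$method == 0) {
      forces
    } else if (!is.null(ns_ref) && !is.null(ns_ref$forces)) {
      ns_ref$forces
    } else {
      group_forces(ns_fir, pool, twitches, saturate = config$saturate)
    }
    traces <- c(lapply(.mu_types, function(ty) forces$group[, ty]),
                list(forces$muscle))
    ns_traces <- c(lapply(.mu_types, function(ty) ns_forces$group[, ty]),
                   list(ns_forces$muscle))
    rows <- lapply(seq_along(traces), function(k) {
      st <- force_stats(traces[[k]], window)
      data.frame(group = c(.mu_types, "muscle")[k],
                 meanF = st$meanF, rmsF = st$rmsF, rangeF = st$rangeF,
                 maxF = st$maxF,
                 meanfreq = mean_freq(force_psd(traces[[k]], window)),
                 vaf = vaf(traces[[k]], ns_traces[[k]], window))
    })
    res$forces <- forces
    res$stats <- do.call(rbind, rows)
  }
  structure(res, class = "scenario_result")
}

#' Run the full synchronization grid
#'
#' Runs the NS scenario plus every requested method x window combination
#' for each seed, reusing the NS firing set and forces of each seed, and
#' aggregates across seeds into three tables: the synchronization indices
#' (corMU and CISI mean +/- SD by group), the six force statistics by
#' group, and the correlations between the CISI trend and each force
#' parameter trend across the window settings.
#'
#' @param seeds integer vector of master seeds.
#' @param methods synchronization methods to run (subset of 1:4).
#' @param windows synchronization half-windows in ms.
#' @param pool a \code{mu_pool}.
#' @param base a \code{scenario_config} supplying all other settings.
#' @param with_forces compute force tables (disable for a sync-only grid).
#' @param progress print one line per scenario.
#' @return A \code{grid_result}: list of data frames \code{sync_table}
#'   (method, window, group, corMU_mean/sd, cisi_mean/sd), and when forces
#'   are enabled \code{force_table} (method, window, group, six
#'   parameters) and \code{trend_table} (method, group, correlation of
#'   each parameter trend with the CISI trend); all values are averaged
#'   over seeds (method 0 rows are the NS baseline).
#' @export
run_grid <- function(seeds = 1:10, methods = 1:4, windows = c(2, 4, 6),
                     pool = load_pool(), base = scenario_config(),
                     with_forces = TRUE, progress = FALSE) {
  stopifnot(length(seeds) >= 1)
  twitches <- if (with_forces) fit_twitch_pool(pool) else NULL
  scen <- rbind(data.frame(method = 0, window = 0),
                expand.grid(window = windows, method = methods)[, c("method", "window")])
  sync_acc <- list()
  force_acc <- list()
  for (seed in seeds) {
    ns <- NULL
    for (k in seq_len(nrow(scen))) {
      cfg <- base
      cfg$method <- scen$method[k]
      cfg$window <- scen$window[k]
      cfg$seed <- seed
      if (progress) {
        message(sprintf("seed %d method %d window %d",
                        seed, cfg$method, cfg$window))
      }
      res <- run_scenario(cfg, pool, twitches, ns_ref = ns,
                          with_forces = with_forces)
      if (cfg$method == 0) ns <- res
      key <- sprintf("%d_%d_%d", seed, cfg$method, cfg$window)
      cs <- res$sync$cor_summary
      ci <- res$sync$cisi_summary
      sync_acc[[key]] <- data.frame(seed = seed, method = cfg$method,
                                    window = cfg$window, group = cs$group,
                                    corMU_mean = cs$mean, corMU_sd = cs$sd,
                                    cisi_mean = ci$mean, cisi_sd = ci$sd)
      if (with_forces) {
        force_acc[[key]] <- cbind(seed = seed, method = cfg$method,
                                  window = cfg$window, res$stats)
      }
    }
  }
  sync_all <- do.call(rbind, sync_acc)
  agg <- function(df, cols) {
    stats::aggregate(df[cols], df[c("method", "window", "group")], mean)
  }
  sync_table <- agg(sync_all, c("corMU_mean", "corMU_sd", "cisi_mean", "cisi_sd"))
  out <- list(sync_table = sync_table[order(sync_table$method, sync_table$window), ],
              per_seed_sync = sync_all, seeds = seeds)
  if (with_forces) {
    force_all <- do.call(rbind, force_acc)
    fcols <- c("meanF", "rmsF", "rangeF", "maxF", "meanfreq", "vaf")
    force_table <- agg(force_all, fcols)
    out$force_table <- force_table[order(force_table$method, force_table$window), ]
    out$per_seed_force <- force_all
    out$trend_table <- .trend_table(out$sync_table, out$force_table, methods)
  }
  class(out) <- "grid_result"
  out
}

## Table of CISI-vs-parameter trend correlations: one row per method and
## group, computed on the seed-averaged 4-point curves (NS baseline plus
## the three windows).  Force groups S/FR/FF pair with the typed CISI; the
## muscle force pairs with the all-unit CISI.
.trend_table <- function(sync_table, force_table, methods) {
  rows <- list()
  for (m in methods) {
    for (g in c(.mu_types, "muscle")) {
      cg <- if (g == "muscle") "all" else g
      base_s <- sync_table[sync_table$method == 0 & sync_table$group == cg, ]
      meth_s <- sync_table[sync_table$method == m & sync_table$group == cg, ]
      base_f <- force_table[force_table$method == 0 & force_table$group == g, ]
      meth_f <- force_table[force_table$method == m & force_table$group == g, ]
      s <- rbind(base_s, meth_s[order(meth_s$window), ])
      f <- rbind(base_f, meth_f[order(meth_f$window), ])
      curves <- cbind(cisi = s$cisi_mean,
                      f[c("meanF", "rmsF", "rangeF", "maxF", "meanfreq", "vaf")])
      rows[[paste(m, g)]] <- cbind(data.frame(method = m, group = g),
                                   as.data.frame(t(trend_correlation(curves))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
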