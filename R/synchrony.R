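## Imposing short-term synchronization: the pulse-shifting rule and the
## four pair-selection schemes.

## nearest value in sorted vector p for each x; ties resolve to the earlier
## (smaller) element.  Returns the nearest values (NA when p is empty).
.nearest_sorted <- function(x, p) {
  if (!length(p)) return(rep(NA_real_, length(x)))
  idx <- findInterval(x, p)
  lo <- ifelse(idx >= 1, p[pmax(idx, 1L)], -Inf)
  hi <- ifelse(idx < length(p), p[pmin(idx + 1L, length(p))], Inf)
  ifelse(x - lo <= hi - x, lo, hi)
}

## region of the protected analysis window: 0 before, 1 inside, 2 after
.window_region <- function(t, protect) {
  (t >= protect[1]) + (t >= protect[2])
}

#' Synchronize one target train to a reference train
#'
#' Each target pulse is assigned to its nearest reference pulse (ties to the
#' earlier one).  A pulse whose offset to that reference is at most
#' \code{dt} ms is moved onto the reference time, subject to two rules:
#' (a) at most one target pulse may occupy any reference pulse -- the
#' nearest candidate wins and the others stay; (b) a move that would carry a
#' pulse across a boundary of the protected analysis window (in either
#' direction) is skipped, which keeps the pulse count inside the window
#' constant.  Pulses are moved, never duplicated or deleted.
#'
#' @param reference,target integer pulse times in ms (1-ms grid).
#' @param dt synchronization half-window, ms (>= 1).
#' @param protect half-open window whose pulse counts must be conserved.
#' @return List with \code{train} (the shifted target, strictly increasing)
#'   and \code{n_shifted} (number of pulses actually moved).
#' @export
#' @examples
#' sync_pair(c(100, 120, 140), c(103, 111, 138), dt = 4,
#'           protect = c(0, 4000))
sync_pair <- function(reference, target, dt, protect = c(2000, 4000)) {
  if (dt < 1) stop("dt must be >= 1 ms")
  if (!length(target) || !length(reference)) {
    return(list(train = as.integer(target), n_shifted = 0L))
  }
  x <- as.integer(target)
  near <- .nearest_sorted(x, as.integer(reference))
  off <- x - near
  eligible <- !is.na(near) & is.finite(near) & abs(off) <= dt &
    .window_region(x, protect) == .window_region(near, protect)
  moved <- logical(length(x))
  if (any(eligible)) {
    cand <- which(eligible)
    ## nearest wins per reference pulse; ties to the earlier target pulse
    cand <- cand[order(abs(off[cand]), x[cand])]
    winners <- cand[!duplicated(near[cand])]
    moved[winners] <- TRUE
  }
  out <- x
  out[moved] <- as.integer(near[moved])
  out <- sort(out)
  if (any(diff(out) <= 0)) {
    stop("internal error: duplicate pulse time after synchronization")
  }
  list(train = out, n_shifted = sum(moved & off != 0L))
}

#' Pair schedule for one synchronization method
#'
#' Builds the ordered reference/target pair list of the four synchronization
#' schemes.  Pairs always couple units of the same physiological type.
#' \describe{
#'   \item{Method 1}{chained neighbours in twitch-force order: within each
#'     type, unit k is synchronized to the already-synchronized unit k-1.}
#'   \item{Method 2}{chained neighbours after reordering each type by
#'     increasing mean rhythmic rate.}
#'   \item{Method 3}{independent groups of (up to) four consecutive units;
#'     the first unit of each group is the reference for the other three.
#'     Types whose size is not a multiple of four end with a short group.}
#'   \item{Method 4}{the first-recruited unit of each type is the reference
#'     for every other unit of that type.}
#' }
#'
#' @param method integer 1-4.
#' @param pool a \code{mu_pool}.
#' @return A \code{sync_schedule}: data frame with columns \code{reference}
#'   and \code{target} (unit indices, processed top to bottom), with
#'   attributes \code{method} and \code{chained}.
#' @export
schedule_for_method <- function(method, pool) {
  if (!(length(method) == 1 && method %in% 1:4)) stop("method must be 1, 2, 3 or 4")
  pairs <- list()
  for (ty in .mu_types) {
    blk <- sort(pool$index[pool$type == ty])
    if (length(blk) < 2) next
    if (method == 1) {
      p <- cbind(blk[-length(blk)], blk[-1])
    } else if (method == 2) {
      ord <- blk[order(pool$meanfr[match(blk, pool$index)], blk)]
      p <- cbind(ord[-length(ord)], ord[-1])
    } else if (method == 3) {
      p <- do.call(rbind, lapply(split(blk, (seq_along(blk) - 1) %/% 4), function(g) {
        if (length(g) < 2) NULL else cbind(g[1], g[-1])
      }))
    } else {
      p <- cbind(blk[1], blk[-1])
    }
    pairs[[ty]] <- p
  }
  sched <- as.data.frame(do.call(rbind, pairs))
  names(sched) <- c("reference", "target")
  rownames(sched) <- NULL
  structure(sched, class = c("sync_schedule", "data.frame"),
            method = method, chained = method %in% c(1, 2))
}

#' Apply a synchronization schedule to a firing set
#'
#' Processes the scheduled pairs in order with \code{\link{sync_pair}}.  The
#' reference train of every pair is taken from the current (possibly
#' already synchronized) state, which realizes the chained scheme of
#' Methods 1 and 2; in Methods 3 and 4 references are never targets, so the
#' distinction is moot.  Untouched units pass through unchanged.
#'
#' @param firings a \code{firing_set}.
#' @param schedule a \code{sync_schedule}.
#' @param dt synchronization half-window, ms.
#' @param pool the \code{mu_pool} the schedule indices refer to.
#' @param protect half-open analysis window with conserved pulse counts.
#' @return A new \code{firing_set} with provenance
#'   \code{"method<m>/dt<dt>"} and a \code{shift_log} data frame
#'   (\code{reference}, \code{target}, \code{n_shifted}).
#' @export
apply_method <- function(firings, schedule, dt, pool, protect = c(2000, 4000)) {
  trains <- firings$trains
  lab <- pool$label[match(c(schedule$reference, schedule$target), pool$index)]
  if (anyNA(lab) || !all(lab %in% names(trains))) {
    stop("schedule references a unit absent from the firing set")
  }
  n_shifted <- integer(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    ref_lab <- pool$label[match(schedule$reference[k], pool$index)]
    tgt_lab <- pool$label[match(schedule$target[k], pool$index)]
    res <- sync_pair(trains[[ref_lab]], trains[[tgt_lab]], dt, protect)
    trains[[tgt_lab]] <- res$train
    n_shifted[k] <- res$n_shifted
  }
  structure(list(trains = trains, seed = firings$seed,
                 duration_ms = firings$duration_ms,
                 provenance = sprintf("method%d/dt%d", attr(schedule, "method"), dt),
                 shift_log = data.frame(reference = schedule$reference,
                                        target = schedule$target,
                                        n_shifted = n_shifted)),
            class = "firing_set")
}
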