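## Quantifying synchronization: binary-series correlation, cross-intervals,
## cross-interval histograms and the cross-interval synchronization index.

#' Binary-train correlation index
#'
#' Normalized correlation of two binary 1-ms series,
#' \deqn{corMU = 100 \cdot \frac{\sum_i a_i b_i}
#'   {\sqrt{\sum_i a_i^2 \cdot \sum_i b_i^2}}\,[\%],}
#' which for binary series is 100 times the number of coincident samples
#' over the geometric mean of the pulse counts.  It does not depend on the
#' series length or on the mean firing rates, so units of different types
#' compare without bias.  Returns 0 when either series is all zero.
#'
#' @param a,b equal-length binary vectors (see \code{\link{binarize}}).
#' @return Percent in [0, 100].
#' @export
cor_mu <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  sa <- sum(a * a)
  sb <- sum(b * b)
  if (sa == 0 || sb == 0) return(0)
  100 * sum(a * b) / sqrt(sa * sb)
}

#' Pairwise correlation matrix of a firing set
#'
#' @param firings a \code{firing_set}.
#' @param window half-open analysis window in ms.
#' @return Symmetric matrix of \code{\link{cor_mu}} values in percent,
#'   ordered and labelled by unit; the diagonal is 100 for every unit with
#'   at least one pulse in the window.
#' @export
cor_matrix <- function(firings, window = c(2000, 4000)) {
  B <- .binarize_set(firings, window)
  n <- rowSums(B)
  C <- tcrossprod(B)
  denom <- sqrt(outer(n, n))
  M <- ifelse(denom > 0, 100 * C / denom, 0)
  dimnames(M) <- list(names(firings$trains), names(firings$trains))
  M
}

#' Cross-intervals between two spike trains
#'
#' For each reference pulse \eqn{t1_x} in the window, the signed
#' cross-interval \eqn{CI_x = t1_x - t2_{xy}} to the nearest partner pulse
#' \eqn{t2_{xy}} in the window (the argmin of \eqn{|t1_x - t2_y|}).  A
#' reference pulse exactly equidistant from two partner pulses takes the
#' earlier one, giving a positive interval (deterministic tie rule).
#'
#' @param reference,partner integer pulse times in ms.
#' @param window half-open analysis window in ms.
#' @return A \code{cross_intervals} object: list with integer \code{values}
#'   (one per reference pulse in the window; negative when the reference
#'   pulse precedes its neighbour) and \code{n_reference}.  \code{values} is
#'   empty when the partner has no pulse in the window.
#' @export
#' @examples
#' cross_intervals(c(2010, 2020, 2030), c(2011, 2019, 2031))$values
cross_intervals <- function(reference, partner, window = c(2000, 4000)) {
  r <- reference[reference >= window[1] & reference < window[2]]
  p <- partner[partner >= window[1] & partner < window[2]]
  if (!length(r)) stop("reference train has no pulse in the window")
  if (!length(p)) {
    return(structure(list(values = integer(0), n_reference = length(r)),
                     class = "cross_intervals"))
  }
  near <- .nearest_sorted(r, p)
  structure(list(values = as.integer(r - near), n_reference = length(r)),
            class = "cross_intervals")
}

#' Cross-interval histogram
#'
#' Bins the cross-intervals at a 1-ms resolution with bin centres at
#' \code{-half_range .. +half_range} ms; bin \eqn{b} covers
#' \eqn{[b - 0.5, b + 0.5)} and its value is the count divided by the
#' number of reference pulses, so the bin values sum to 1 whenever every
#' cross-interval lies within the covered range.
#'
#' @param ci a \code{cross_intervals} object.
#' @param half_range covered lag range, ms.
#' @return Data frame with columns \code{center_ms} and \code{prob}.
#' @export
ci_histogram <- function(ci, half_range = 15) {
  centers <- seq(-half_range, half_range)
  counts <- vapply(centers, function(b) sum(ci$values == b), integer(1))
  data.frame(center_ms = centers, prob = counts / ci$n_reference)
}

#' Central-bin coincidence probability
#'
#' Probability that a reference pulse coincides with its nearest partner
#' pulse within the central histogram bin (+/- 0.5 ms; on the integer grid,
#' a cross-interval of exactly 0).
#'
#' @param ci a \code{cross_intervals} object.
#' @return Probability in [0, 1].
#' @export
central_bin_prob <- function(ci) {
  sum(ci$values == 0L) / ci$n_reference
}

#' Cross-interval synchronization index of one unit
#'
#' \deqn{CISI(MU_i) = \frac{100}{N-1} \sum_{j \ne i}
#'   \frac{c_0\{CI(MU_i, MU_j)\}}{n_{MU_i}}\,[\%],}
#' the central-bin coincidence probability of unit \eqn{i} averaged over all
#' \eqn{N-1} partner units; 100% means every reference pulse coincides with
#' a pulse of every partner.  Partners with no pulse in the window
#' contribute zero coincidences.
#'
#' @param firings a \code{firing_set}.
#' @param i position of the reference unit within the firing set.
#' @param window half-open analysis window in ms.
#' @return Percent in [0, 100].
#' @export
cisi <- function(firings, i, window = c(2000, 4000)) {
  trains <- firings$trains
  N <- length(trains)
  tot <- 0
  for (j in seq_len(N)[-i]) {
    ci <- cross_intervals(trains[[i]], trains[[j]], window)
    if (length(ci$values)) tot <- tot + central_bin_prob(ci)
  }
  100 * tot / (N - 1)
}

## Fast equivalent of cisi() for all units at once: on the integer grid a
## zero cross-interval is an exact coincidence of pulse times, so the
## coincidence counts are the pairwise products of the binary series.
.cisi_all <- function(firings, window = c(2000, 4000)) {
  B <- .binarize_set(firings, window)
  n <- rowSums(B)
  C <- tcrossprod(B)
  N <- nrow(B)
  out <- ifelse(n > 0, 100 * (rowSums(C) - n) / ((N - 1) * n), NA_real_)
  names(out) <- names(firings$trains)
  out
}

#' Summarize synchronization over a firing set
#'
#' Computes the full pairwise correlation matrix, the per-unit
#' cross-interval synchronization index, and their aggregates: correlation
#' mean +/- SD over the unordered within-type pairs of each type and over
#' all unordered pairs; CISI (each unit against all partners, of any type)
#' mean +/- SD over the units of each type and over all units.
#'
#' @param firings a \code{firing_set}.
#' @param pool the matching \code{mu_pool}.
#' @param window half-open analysis window in ms.
#' @return A \code{sync_summary}: list with \code{cor_matrix}, \code{cisi}
#'   (named per-unit vector), and data frames \code{cor_summary} and
#'   \code{cisi_summary} (columns \code{group}, \code{mean}, \code{sd},
#'   \code{n}; groups S, FR, FF, all).
#' @export
summarize_sync <- function(firings, pool, window = c(2000, 4000)) {
  M <- cor_matrix(firings, window)
  cis <- .cisi_all(firings, window)
  groups <- c(.mu_types, "all")
  cor_rows <- lapply(groups, function(g) {
    sel <- if (g == "all") seq_len(nrow(pool)) else which(pool$type == g)
    v <- M[sel, sel][upper.tri(M[sel, sel])]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  cisi_rows <- lapply(groups, function(g) {
    sel <- if (g == "all") seq_len(nrow(pool)) else which(pool$type == g)
    v <- cis[sel]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  structure(list(cor_matrix = M, cisi = cis,
                 cor_summary = do.call(rbind, cor_rows),
                 cisi_summary = do.call(rbind, cisi_rows),
                 provenance = firings$provenance),
            class = "sync_summary")
}

#' @export
print.sync_summary <- function(x, ...) {
  cat("Synchronization summary (", x$provenance, ")\n", sep = "")
  cat("corMU [%] over unordered pairs:\n")
  print(x$cor_summary, row.names = FALSE, digits = 3)
  cat("CISI [%] over units:\n")
  print(x$cisi_summary, row.names = FALSE, digits = 3)
  invisible(x)
}
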