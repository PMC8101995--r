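## Motor-unit pool: the 57-unit parameter table, validation and tabular I/O.

.pool_columns <- c("index", "label", "type", "Tc", "Thr", "Ttw",
                   "Fmax", "Fmftf", "meanfr", "minfr", "maxfr")
.pool_numeric <- setdiff(.pool_columns, c("label", "type"))
.mu_types <- c("S", "FR", "FF")
.builtin_counts <- c(S = 8L, FR = 23L, FF = 26L)

#' Load a motor-unit pool
#'
#' Reads the contractile and firing parameters of a motor-unit pool from a
#' CSV file, or returns the packaged 57-unit rat medial gastrocnemius table
#' when \code{source = "builtin"}.  Units are ordered by \code{index}; in the
#' builtin pool indices 1-8 are the slow (S) units, 9-31 the fast
#' fatigue-resistant (FR) units and 32-57 the fast fatigable (FF) units,
#' numbered within each type by increasing maximum twitch force.
#'
#' @param source path to a CSV file with columns
#'   \code{index,label,type,Tc,Thr,Ttw,Fmax,Fmftf,meanfr,minfr,maxfr}
#'   (times in ms, forces in mN, rates in Hz), or the token \code{"builtin"}.
#' @return A \code{mu_pool} object: a data frame with one row per unit.
#' @seealso \code{\link{validate_pool}}, \code{\link{write_pool}}
#' @export
#' @examples
#' pool <- load_pool()
#' table(pool$type)
load_pool <- function(source = "builtin") {
  builtin <- identical(source, "builtin")
  path <- if (builtin) {
    system.file("extdata", "mu_pool.csv", package = "mupoolsim", mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) stop("cannot read pool file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.pool_columns, names(df))
  if (length(missing)) {
    stop("pool file is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (cl in .pool_numeric) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value in column '%s' at row %d",
                   cl, which(is.na(v))[1]))
    }
    df[[cl]] <- v
  }
  dup <- duplicated(df$label)
  if (any(dup)) {
    stop(sprintf("duplicate unit label '%s' at row %d",
                 df$label[dup][1], which(dup)[1]))
  }
  df <- df[order(df$index), .pool_columns]
  rownames(df) <- NULL
  structure(df, class = c("mu_pool", "data.frame"), builtin = builtin)
}

#' Write a motor-unit pool to CSV
#'
#' Inverse of \code{\link{load_pool}}: \code{load_pool(write_pool(pool, f))}
#' reproduces \code{pool}.
#'
#' @param pool a \code{mu_pool}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pool <- function(pool, path) {
  utils::write.csv(as.data.frame(pool)[, .pool_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a motor-unit pool
#'
#' Checks per-unit invariants (all parameters positive, minfr < meanfr <
#' maxfr, Fmax < Fmftf, Ttw >= Tc) and pool-level invariants (unique labels,
#' Fmax nondecreasing with index within each type; for a pool flagged as the
#' complete builtin table, the 8/23/26 type counts).  Violations are
#' reported, not raised.
#'
#' @param pool a \code{mu_pool}.
#' @param builtin_complete if \code{TRUE}, additionally require the full
#'   57-unit composition of the builtin pool.  Defaults to the provenance
#'   recorded by \code{\link{load_pool}}.
#' @return A data frame with columns \code{label} and \code{violation};
#'   zero rows when the pool is clean.
#' @export
validate_pool <- function(pool, builtin_complete = isTRUE(attr(pool, "builtin"))) {
  bad <- list()
  flag <- function(label, violation) {
    bad[[length(bad) + 1L]] <<- data.frame(label = label, violation = violation,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pool))) {
    u <- pool[i, ]
    if (any(unlist(u[.pool_numeric]) <= 0)) flag(u$label, "non-positive parameter")
    if (!(u$minfr < u$meanfr && u$meanfr < u$maxfr)) {
      flag(u$label, "firing rates not ordered minfr < meanfr < maxfr")
    }
    if (!(u$Fmax < u$Fmftf)) flag(u$label, "Fmax not below Fmftf")
    if (u$Ttw < u$Tc) flag(u$label, "twitch duration shorter than contraction time")
    if (!(u$type %in% .mu_types)) flag(u$label, "unknown type")
  }
  dup <- unique(pool$label[duplicated(pool$label)])
  for (d in dup) flag(d, "duplicate label")
  for (ty in .mu_types) {
    f <- pool$Fmax[pool$type == ty][order(pool$index[pool$type == ty])]
    if (is.unsorted(f)) flag(ty, "Fmax not nondecreasing with index within type")
  }
  if (builtin_complete) {
    cnt <- table(factor(pool$type, levels = .mu_types))
    for (ty in .mu_types) {
      if (cnt[[ty]] != .builtin_counts[[ty]]) {
        flag(ty, sprintf("expected %d units of type %s, found %d",
                         .builtin_counts[[ty]], ty, cnt[[ty]]))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad) else {
    data.frame(label = character(0), violation = character(0))
  }
}

#' @export
print.mu_pool <- function(x, ...) {
  cnt <- table(factor(x$type, levels = .mu_types))
  cat(sprintf("Motor-unit pool: %d units (%s)\n", nrow(x),
              paste(sprintf("%d %s", cnt, names(cnt)), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}
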