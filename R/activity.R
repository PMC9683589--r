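#' Per-minute activity matrix
#'
#' The basic container of the package: per-minute locomotor counts for a set of
#' flies on a uniform time grid. Rows are minutes, columns are flies. Rows can
#' be flagged invalid (monitor error or a gap in the recording); invalid rows
#' carry `NA` counts so no downstream statistic can use them silently.
#'
#' @param timestamps `POSIXct` vector, strictly increasing with constant
#'   spacing of `interval_min` minutes.
#' @param counts integer matrix (or vector for a single fly), one column per
#'   fly, non-negative. Rows flagged invalid are forced to `NA`.
#' @param valid logical vector, one entry per row; default all `TRUE`.
#' @param fly_ids character vector of stable fly identifiers; default
#'   `fly_001`, `fly_002`, ...
#' @param interval_min acquisition interval in minutes (1 for DAM2).
#'
#' @return An object of class `activity_matrix`: a list with elements
#'   `timestamps`, `counts`, `valid`, `fly_ids`, `interval_min`.
#' @export
activity_matrix <- function(timestamps, counts, valid = NULL, fly_ids = NULL,
                            interval_min = 1) {
  if (!inherits(timestamps, "POSIXct")) {
    stop("`timestamps` must be POSIXct")
  }
  counts <- as.matrix(counts)
  n <- length(timestamps)
  if (nrow(counts) != n) {
    stop("`counts` must have one row per timestamp")
  }
  if (n > 1) {
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0)) stop("`timestamps` must be strictly increasing")
    if (any(abs(d - interval_min * 60) > 1e-6)) {
      stop("`timestamps` must be uniformly spaced at `interval_min` minutes")
    }
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("`valid` must have one entry per row")
  if (is.null(fly_ids)) {
    fly_ids <- sprintf("fly_%03d", seq_len(ncol(counts)))
  }
  if (length(fly_ids) != ncol(counts)) {
    stop("number of count columns must equal number of fly ids")
  }
  if (anyDuplicated(fly_ids)) stop("`fly_ids` must be unique")
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  counts[!valid, ] <- NA_integer_
  dimnames(counts) <- list(NULL, fly_ids)
  structure(
    list(timestamps = timestamps, counts = counts, valid = valid,
         fly_ids = fly_ids, interval_min = interval_min),
    class = "activity_matrix"
  )
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf(
    "<activity_matrix> %d flies x %d minutes (%s -- %s), %d invalid rows\n",
    length(x$fly_ids), length(x$timestamps),
    format(min(x$timestamps), "%Y-%m-%d %H:%M"),
    format(max(x$timestamps), "%Y-%m-%d %H:%M"),
    sum(!x$valid)
  ))
  invisible(x)
}

#' @export
dim.activity_matrix <- function(x) dim(x$counts)

#' Subset an activity matrix by fly
#'
#' Column-subsets (and reorders) an [activity_matrix()] to the requested fly
#' identifiers. Timestamps and validity flags are retained.
#'
#' @param matrix an [activity_matrix()].
#' @param ids character vector of fly identifiers, a subset of
#'   `matrix$fly_ids`; the output column order follows `ids`.
#' @return An `activity_matrix` with `length(ids)` columns.
#' @export
select_flies <- function(matrix, ids) {
  stopifnot(inherits(matrix, "activity_matrix"))
  unknown <- setdiff(ids, matrix$fly_ids)
  if (length(unknown) > 0) {
    stop("unknown fly id(s): ", paste(unknown, collapse = ", "))
  }
  counts <- matrix$counts[, match(ids, matrix$fly_ids), drop = FALSE]
  out <- matrix
  out$counts <- counts
  out$fly_ids <- as.character(ids)
  if (length(ids) > 0) colnames(out$counts) <- out$fly_ids
  out
}

#' Restrict an activity matrix to a time window
#'
#' @param matrix an [activity_matrix()].
#' @param from,to `POSIXct` bounds; rows with `from <= t < to` are kept.
#' @return An `activity_matrix`.
#' @export
slice_time <- function(matrix, from, to) {
  stopifnot(inherits(matrix, "activity_matrix"))
  keep <- matrix$timestamps >= from & matrix$timestamps < to
  if (!any(keep)) stop("no rows in the requested time window")
  out <- matrix
  out$timestamps <- matrix$timestamps[keep]
  out$counts <- matrix$counts[keep, , drop = FALSE]
  out$valid <- matrix$valid[keep]
  out
}
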