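#' Sum per-minute counts into fixed-width bins
#'
#' Bins the one-minute grid into consecutive `bin_minutes` windows starting at
#' `origin` (by default the first timestamp; pass a day's ZT0 to get ZT-aligned
#' bins). Each bin value is the sum of the valid per-minute counts in
#' `[bin_start, bin_start + bin_minutes)`. Bins not fully covered by the
#' recording are dropped; bins with more than 50% invalid minutes are `NA`.
#'
#' @param matrix an [activity_matrix()].
#' @param bin_minutes bin width in minutes; must divide 1440.
#' @param origin `POSIXct` bin-grid origin. Bins start at
#'   `origin + k * bin_minutes` for integer `k` (negative `k` allowed), so the
#'   origin may lie inside the recording.
#' @return An object of class `binned_activity`: list with `bin_start`
#'   (`POSIXct`), `counts` (bins x flies, `NA` = missing), `fly_ids`,
#'   `bin_minutes`.
#' @export
bin_counts <- function(matrix, bin_minutes = 30, origin = NULL) {
  stopifnot(inherits(matrix, "activity_matrix"))
  if (1440 %% bin_minutes != 0) {
    stop("`bin_minutes` must divide 1440")
  }
  if (matrix$interval_min != 1) {
    stop("binning expects 1-minute acquisition")
  }
  if (is.null(origin)) origin <- matrix$timestamps[1]
  rel <- round(as.numeric(matrix$timestamps) - as.numeric(origin)) / 60
  j <- floor(rel / bin_minutes)
  n_in_bin <- table(j)
  keep_j <- as.numeric(names(n_in_bin))[n_in_bin == bin_minutes]
  keep_j <- sort(keep_j)
  if (length(keep_j) == 0) stop("recording shorter than one bin")
  grp <- match(j, keep_j)
  inb <- !is.na(grp)
  cnt <- matrix$counts[inb, , drop = FALSE]
  cnt[is.na(cnt)] <- 0L
  sums <- rowsum(cnt, grp[inb], reorder = TRUE)
  n_invalid <- rowsum((!matrix$valid[inb]) * 1L, grp[inb], reorder = TRUE)[, 1]
  sums[n_invalid / bin_minutes > 0.5, ] <- NA
  bin_start <- origin + keep_j * bin_minutes * 60
  structure(
    list(bin_start = bin_start,
         counts = matrix(as.numeric(sums), nrow(sums), ncol(sums),
                         dimnames = list(NULL, matrix$fly_ids)),
         fly_ids = matrix$fly_ids, bin_minutes = bin_minutes),
    class = "binned_activity"
  )
}

#' Normalize binned activity to each fly's maximum
#'
#' Divides every fly's bins by that fly's maximum bin over the normalization
#' window and scales to percent, so each included fly attains 100 in at least
#' one window bin. Flies whose window maximum is zero (or all-missing) carry no
#' usable signal and are excluded, and reported in the `excluded` element
#' rather than by an error.
#'
#' @param binned a [bin_counts()] result.
#' @param window integer indices of the bins the maximum is taken over
#'   (default: all bins, i.e. the fly's whole binned recording).
#' @return An object of class `normalized_activity`: list with `bin_start`,
#'   `zt` (`NA` until a day grid is attached, see [daily_profile()]), `values`
#'   (bins x flies, percent of each fly's max), `fly_ids`, `bin_minutes`,
#'   `excluded` (character vector of dropped fly ids).
#' @export
normalize_activity <- function(binned, window = NULL) {
  stopifnot(inherits(binned, "binned_activity"))
  if (is.null(window)) window <- seq_along(binned$bin_start)
  if (length(window) == 0) stop("normalization window is empty")
  mx <- suppressWarnings(apply(binned$counts[window, , drop = FALSE], 2, max,
                               na.rm = TRUE))
  drop <- !is.finite(mx) | mx <= 0
  vals <- sweep(binned$counts[, !drop, drop = FALSE], 2, mx[!drop], "/") * 100
  structure(
    list(bin_start = binned$bin_start, zt = rep(NA_real_, length(binned$bin_start)),
         values = vals, fly_ids = binned$fly_ids[!drop],
         bin_minutes = binned$bin_minutes,
         excluded = binned$fly_ids[drop]),
    class = "normalized_activity"
  )
}

#' Population median activity profile
#'
#' Per-bin median of normalized activity across flies; the median rather than
#' the mean is used because it reflects what the typical fly does and is
#' therefore a measure of behavioral synchrony. Defined only on bins where at
#' least one fly has valid data.
#'
#' @param norm a [normalize_activity()] result (with a ZT grid attached for
#'   landmark work, see [daily_profile()]).
#' @return An object of class `population_profile`: list with `zt` (bin start,
#'   ZT minutes), `bin_start`, `median_value`, `n_flies` (flies with data per
#'   bin), `bin_minutes`.
#' @export
median_profile <- function(norm) {
  stopifnot(inherits(norm, "normalized_activity"))
  med <- apply(norm$values, 1, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  n <- rowSums(!is.na(norm$values))
  structure(
    list(zt = norm$zt, bin_start = norm$bin_start, median_value = med,
         n_flies = n, bin_minutes = norm$bin_minutes),
    class = "population_profile"
  )
}

#' Restrict an activity matrix to one analysis day
#'
#' Returns the rows spanning exactly ZT0 to ZT0 + 1440 min of the requested
#' protocol day. Accepted day specifiers: `"last_LD"` (the final LD day, the
#' conventional LD analysis day), `"TC<k>"` (k-th full temperature-cycle day,
#' e.g. `"TC6"`), `"DD<k>"` (k-th free-running constant day after the cycles),
#' or any exact [protocol_days()] label.
#'
#' @param matrix an [activity_matrix()].
#' @param protocol a `protocol`.
#' @param which day specifier (see above).
#' @return An `activity_matrix` of 1440 rows.
#' @export
select_analysis_day <- function(matrix, protocol, which) {
  day <- resolve_day(protocol, which)
  if (matrix$timestamps[1] > day$start ||
      matrix$timestamps[length(matrix$timestamps)] < day$end - 60) {
    stop("recording does not cover day ", day$label)
  }
  slice_time(matrix, day$start, day$end)
}

resolve_day <- function(protocol, which) {
  days <- protocol_days(protocol)
  if (identical(which, "last_LD") || identical(which, "LD_last")) {
    ld <- days[days$role == "ld", ]
    if (nrow(ld) == 0) stop("protocol has no LD days")
    return(ld[nrow(ld), ])
  }
  m <- regmatches(which, regexec("^(TC|DD)_?(?:day_?)?([0-9]+)$", which))[[1]]
  if (length(m) == 3) {
    role <- if (m[2] == "TC") "tc" else "free"
    sel <- days[days$role == role & days$index == as.integer(m[3]), ]
    if (nrow(sel) != 1) {
      stop("protocol has no ", m[2], " day ", m[3])
    }
    return(sel)
  }
  sel <- days[days$label == which, ]
  if (nrow(sel) != 1) stop("unknown analysis day '", which, "'")
  sel
}

#' Drop flies without any activity in a window
#'
#' Flies recording zero counts over the window (typically dead or escaped) are
#' removed before analysis. A single count is enough to retain a fly.
#'
#' @param matrix an [activity_matrix()].
#' @param from,to optional `POSIXct` window bounds (default: whole recording).
#' @return List with `matrix` (the surviving flies) and `excluded` (dropped ids).
#' @export
exclude_dead_flies <- function(matrix, from = NULL, to = NULL) {
  stopifnot(inherits(matrix, "activity_matrix"))
  win <- matrix
  if (!is.null(from) || !is.null(to)) {
    if (is.null(from)) from <- matrix$timestamps[1]
    if (is.null(to)) to <- matrix$timestamps[length(matrix$timestamps)] + 60
    win <- slice_time(matrix, from, to)
  }
  tot <- colSums(win$counts, na.rm = TRUE)
  dead <- matrix$fly_ids[tot == 0]
  list(matrix = select_flies(matrix, setdiff(matrix$fly_ids, dead)),
       excluded = dead)
}

#' One analysis day: normalized activity and median profile
#'
#' The standard preparation behind every slope analysis: bin the whole
#' recording on the analysis day's ZT grid, normalize each fly to its maximum
#' (by default over the entire recording, so different analysis days of one
#' experiment share a scale), and return the day's normalized activity together
#' with its population median profile. Bin timestamps refer to the bin start:
#' the value at ZT 690 covers minutes 690-719.
#'
#' @param matrix an [activity_matrix()].
#' @param protocol a `protocol`.
#' @param day day specifier, see [select_analysis_day()].
#' @param bin_minutes bin width (default 30).
#' @param normalize_window `"recording"` (default) to take each fly's maximum
#'   over the whole binned recording, or `"day"` to renormalize within the
#'   analysis day only.
#' @return List with `norm` (the day's [normalize_activity()] values, ZT grid
#'   attached), `profile` (its [median_profile()]), `day` (the resolved
#'   [protocol_days()] row) and `excluded` (flies dropped at normalization).
#' @export
daily_profile <- function(matrix, protocol, day, bin_minutes = 30,
                          normalize_window = c("recording", "day")) {
  normalize_window <- match.arg(normalize_window)
  day_row <- resolve_day(protocol, day)
  binned <- bin_counts(matrix, bin_minutes, origin = day_row$start)
  rel <- round(as.numeric(binned$bin_start) - as.numeric(day_row$start)) / 60
  in_day <- which(rel >= 0 & rel < 1440)
  if (length(in_day) < 1440 / bin_minutes) {
    stop("recording does not cover day ", day_row$label)
  }
  win <- if (normalize_window == "recording") NULL else in_day
  norm <- normalize_activity(binned, window = win)
  norm$bin_start <- norm$bin_start[in_day]
  norm$values <- norm$values[in_day, , drop = FALSE]
  norm$zt <- rel[in_day]
  norm$day_label <- day_row$label
  list(norm = norm, profile = median_profile(norm), day = day_row,
       excluded = norm$excluded)
}
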