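# Trikinetics DAM2 text format: one row per reading, 42 tab-separated fields.
#   1     reading index
#   2     date "d mmm yy" (English month abbreviation, case-insensitive)
#   3     time "HH:MM:SS"
#   4     monitor status code (1 = valid reading)
#   5-10  device metadata / light-sensor fields
#   11-42 activity counts for channels 1-32
# This is the only dialect supported; files are validated strictly rather than
# guessed at.

.DAM_MONTHS <- c("jan", "feb", "mar", "apr", "may", "jun",
                 "jul", "aug", "sep", "oct", "nov", "dec")
.DAM_MONTHS_OUT <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                     "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

.parse_dam_datetime <- function(date_str, time_str, row) {
  dp <- strsplit(trimws(date_str), " +")[[1]]
  if (length(dp) != 3) stop("row ", row, ": unparseable date '", date_str, "'")
  day <- suppressWarnings(as.integer(dp[1]))
  mon <- match(tolower(dp[2]), .DAM_MONTHS)
  yy <- suppressWarnings(as.integer(dp[3]))
  if (is.na(day) || is.na(mon) || is.na(yy)) {
    stop("row ", row, ": unparseable date '", date_str, "'")
  }
  if (!grepl("^[0-9]{2}:[0-9]{2}:[0-9]{2}$", time_str)) {
    stop("row ", row, ": unparseable time '", time_str, "'")
  }
  out <- as.POSIXct(sprintf("%04d-%02d-%02d %s", 2000L + yy, mon, day, time_str),
                    tz = "UTC")
  if (is.na(out)) stop("row ", row, ": invalid date/time")
  out
}

#' Read a Trikinetics DAM2 monitor file
#'
#' Parses the 42-field tab-separated DAM2 format into an [activity_matrix()]
#' covering the file's full time span. Rows whose status code is not 1 are
#' flagged invalid (their counts become `NA`); minutes missing from the file
#' are filled in as invalid rows so the one-minute grid stays uniform.
#'
#' @param path path to a DAM2 text file.
#' @param monitor monitor name used to build fly identifiers
#'   (`<monitor>_ch01` ... `<monitor>_ch32`); defaults to the file name.
#' @return An [activity_matrix()] with 32 fly channels.
#' @export
read_dam2 <- function(path, monitor = NULL) {
  if (is.null(monitor)) monitor <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fly_ids <- sprintf("%s_ch%02d", monitor, 1:32)
  if (length(lines) == 0) {
    return(activity_matrix(as.POSIXct(character(0), tz = "UTC"),
                           matrix(integer(0), 0, 32), fly_ids = fly_ids))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42)
  if (length(bad) > 0) {
    stop("malformed DAM2 row ", bad[1], ": expected 42 fields, found ", nf[bad[1]])
  }
  ts <- as.POSIXct(vapply(seq_along(fields), function(i) {
    .parse_dam_datetime(fields[[i]][2], fields[[i]][3], i)
  }, numeric(1)), tz = "UTC", origin = "1970-01-01")
  if (length(ts) > 1) {
    d <- diff(as.numeric(ts))
    if (any(d <= 0)) {
      stop("non-monotone timestamps at row ", which(d <= 0)[1] + 1L)
    }
    if (any(d %% 60 != 0)) {
      stop("timestamp spacing is not a whole number of minutes at row ",
           which(d %% 60 != 0)[1] + 1L)
    }
  }
  status <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4)))
  if (anyNA(status)) {
    stop("malformed DAM2 row ", which(is.na(status))[1], ": bad status field")
  }
  cnt <- t(vapply(fields, function(f) {
    suppressWarnings(as.integer(f[11:42]))
  }, integer(32)))
  if (anyNA(cnt)) {
    stop("malformed DAM2 row ", which(rowSums(is.na(cnt)) > 0)[1],
         ": non-integer count field")
  }
  # gap-fill to a uniform 1-min grid
  grid <- seq(ts[1], ts[length(ts)], by = 60)
  idx <- match(as.numeric(grid), as.numeric(ts))
  present <- !is.na(idx)
  counts <- matrix(NA_integer_, length(grid), 32)
  counts[present, ] <- cnt[idx[present], ]
  valid <- present & (status[ifelse(present, idx, 1L)] == 1L)
  activity_matrix(grid, counts, valid = valid, fly_ids = fly_ids)
}

#' Write an activity matrix as a DAM2 monitor file
#'
#' Emits the 42-field DAM2 dialect read by [read_dam2()]. Matrices with fewer
#' than 32 channels are zero-padded to 32; valid rows get status code 1 and
#' invalid rows status code 51 (with zero counts), so a write/read cycle
#' reproduces counts, timestamps and validity exactly, and a second write is
#' byte-identical.
#'
#' @param matrix an [activity_matrix()] with at most 32 channels.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_dam2 <- function(matrix, path) {
  stopifnot(inherits(matrix, "activity_matrix"))
  k <- ncol(matrix$counts)
  if (k > 32) {
    stop("DAM2 holds at most 32 channels per monitor; split the matrix ",
         "across monitor files with select_flies()")
  }
  n <- length(matrix$timestamps)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lt <- as.POSIXlt(matrix$timestamps, tz = "UTC")
  date_str <- sprintf("%d %s %02d", lt$mday, .DAM_MONTHS_OUT[lt$mon + 1L],
                      lt$year %% 100L)
  time_str <- format(matrix$timestamps, "%H:%M:%S", tz = "UTC")
  status <- ifelse(matrix$valid, 1L, 51L)
  cnt <- matrix(0L, n, 32)
  if (k > 0) {
    filled <- matrix$counts
    filled[is.na(filled)] <- 0L
    cnt[, seq_len(k)] <- filled
  }
  meta <- matrix(0L, n, 6)
  rows <- cbind(seq_len(n), date_str, time_str, status, meta, cnt)
  writeLines(apply(rows, 1, paste, collapse = "\t"), path)
  invisible(path)
}
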