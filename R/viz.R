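# Figure functions. These are pure renderings: every statistic they display
# (medians, landmarks, box statistics) comes from the analysis functions or
# from box_stats(), never from ad-hoc computation inside a plot.

.shade_fill <- c("on_25" = "white", "off_25" = "grey70",
                 "on_16" = "#9ecae1", "off_16" = "#4292c6")

# environmental shading rectangles over one ZT day of a protocol day
.day_shading <- function(protocol, day_row, step = 30) {
  zt <- seq(0, 1440 - step, by = step)
  env <- environment_at(day_row$start + zt * 60, protocol)
  key <- paste0(env$light, "_", ifelse(env$temp <= 20, "16", "25"))
  run <- rle(key)
  ends <- cumsum(run$lengths) * step
  data.frame(xmin = c(0, utils::head(ends, -1)), xmax = ends,
             key = run$values, stringsAsFactors = FALSE)
}

#' Daily median-activity profile plot
#'
#' The median normalized activity of one analysis day over its 48 half-hour
#' bins, with environmental shading bars (light/dark, thermophase/cryophase)
#' along the time axis and optional landmark markers.
#'
#' @param profile a [median_profile()] with ZT grid (see [daily_profile()]).
#' @param protocol,day protocol and resolved day row (as returned in
#'   `daily_profile()$day`) used for the shading; omit both for an unshaded
#'   plot.
#' @param landmarks optional [detect_landmarks()] result to mark.
#' @param file optional output path (`.pdf`, `.png`, `.svg`); when given the
#'   figure is also written there.
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_daily_profile <- function(profile, protocol = NULL, day = NULL,
                               landmarks = NULL, file = NULL) {
  stopifnot(inherits(profile, "population_profile"))
  df <- data.frame(zt = profile$zt / 60, value = profile$median_value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$zt, y = .data$value))
  if (!is.null(protocol) && !is.null(day)) {
    sh <- .day_shading(protocol, day)
    p <- p + ggplot2::geom_rect(
      data = sh, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin / 60, xmax = .data$xmax / 60,
                   fill = .data$key),
      ymin = -8, ymax = -2, color = "grey30", linewidth = 0.2,
      show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = .shade_fill)
  }
  p <- p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1)
  if (!is.null(landmarks)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(landmarks$zt_min, landmarks$zt_max) / 60,
      linetype = "dashed", color = "grey40")
  }
  p <- p + ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "ZT (h)", y = "median activity (% of max)") +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 3.2)
    return(invisible(p))
  }
  p
}

#' Double-plotted average actogram
#'
#' One row per recording day showing day d (left half) and day d + 1 (right
#' half), 48 h per row; bar height is the population mean of the normalized
#' activity per bin, over environmental shading. The last row's right half
#' shows nothing beyond the end of the recording.
#'
#' @param norm a [normalize_activity()] result spanning the whole recording
#'   (`bin_start` timestamps; at least 2 full days).
#' @param protocol the experiment's `protocol`, used for shading.
#' @param file optional output path.
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_actogram <- function(norm, protocol, file = NULL) {
  stopifnot(inherits(norm, "normalized_activity"))
  t0 <- protocol$segments$start[1]
  hours <- (as.numeric(norm$bin_start) - as.numeric(t0)) / 3600
  act <- rowMeans(norm$values, na.rm = TRUE)
  keep <- hours >= 0
  hours <- hours[keep]; act <- act[keep]
  day <- floor(hours / 24)
  n_days <- max(day) + 1
  if (n_days < 2) stop("double-plotted actogram needs at least 2 days of data")
  rows <- lapply(seq_len(n_days - 1) - 1, function(d) {
    sel <- day %in% c(d, d + 1)
    data.frame(row = d + 1, x = hours[sel] - d * 24, act = act[sel])
  })
  df <- do.call(rbind, rows)
  span_min <- (as.numeric(protocol$segments$end[nrow(protocol$segments)]) -
                 as.numeric(t0)) / 60
  env <- environment_at(
    t0 + seq(0, min(n_days * 1440, span_min) - 30, by = 30) * 60, protocol)
  key <- paste0(env$light, "_", ifelse(env$temp <= 20, "16", "25"))
  run <- rle(key)
  ends <- cumsum(run$lengths) * 0.5
  sh_abs <- data.frame(from = c(0, utils::head(ends, -1)), to = ends,
                       key = run$values)
  sh <- do.call(rbind, lapply(seq_len(n_days - 1) - 1, function(d) {
    s <- sh_abs
    s$xmin <- pmax(s$from - d * 24, 0)
    s$xmax <- pmin(s$to - d * 24, 48)
    s <- s[s$xmax > s$xmin, ]
    if (nrow(s) == 0) return(NULL)
    s$row <- d + 1
    s
  }))
  mx <- max(act, na.rm = TRUE)
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = sh, ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax, fill = .data$key),
      ymin = 0, ymax = mx, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = .shade_fill) +
    ggplot2::geom_col(data = df, ggplot2::aes(x = .data$x, y = .data$act),
                      width = norm$bin_minutes / 60, fill = "black") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$row)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 12), expand = c(0, 0)) +
    ggplot2::labs(x = "time (h, double-plotted)", y = "mean activity (% of max)") +
    ggplot2::theme_classic() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 0.7 * n_days + 1)
    return(invisible(p))
  }
  p
}

#' Box statistics for slope box plots
#'
#' Quartiles (interpolated), mean, and whiskers at the most extreme values
#' within 1.5 interquartile ranges of the box (Tukey rule); values beyond the
#' whiskers are outliers.
#'
#' @param x numeric vector.
#' @return List: `q1`, `median`, `q3`, `mean`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_stats <- function(x) {
  x <- x[!is.na(x)]
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  inside <- x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr
  list(q1 = q[1], median = q[2], q3 = q[3], mean = mean(x),
       whisker_lo = min(x[inside]), whisker_hi = max(x[inside]),
       outliers = x[!inside])
}

#' Slope box plots by group
#'
#' Box = first quartile / median / third quartile, cross = mean, whiskers =
#' minimum and maximum excluding outliers (beyond 1.5 IQR), outliers drawn as
#' open points.
#'
#' @param groups named list of numeric slope vectors.
#' @param ylab axis label.
#' @param file optional output path.
#' @return A ggplot object, invisibly when `file` is given.
#' @export
plot_slope_box <- function(groups, ylab = "slope (% max / min)", file = NULL) {
  if (is.null(names(groups))) stop("`groups` must be a named list")
  st <- lapply(groups, box_stats)
  df <- data.frame(
    group = factor(names(groups), levels = names(groups)),
    q1 = vapply(st, `[[`, 0, "q1"), med = vapply(st, `[[`, 0, "median"),
    q3 = vapply(st, `[[`, 0, "q3"), mean = vapply(st, `[[`, 0, "mean"),
    lo = vapply(st, `[[`, 0, "whisker_lo"),
    hi = vapply(st, `[[`, 0, "whisker_hi"))
  out <- do.call(rbind, lapply(names(st), function(g) {
    o <- st[[g]]$outliers
    if (length(o) == 0) return(NULL)
    data.frame(group = factor(g, levels = names(groups)), y = o)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.25) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$med, ymin = .data$q1,
                                        ymax = .data$q3),
                           width = 0.5, fill = "white") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), shape = 4, size = 2.5)
  if (!is.null(out)) {
    p <- p + ggplot2::geom_point(data = out, ggplot2::aes(y = .data$y),
                                 shape = 1)
  }
  p <- p + ggplot2::labs(x = NULL, y = ylab) + ggplot2::theme_classic()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 1 + length(groups), height = 3.2)
    return(invisible(p))
  }
  p
}
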