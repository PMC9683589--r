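# Environmental schedule of an entrainment experiment: an ordered list of
# contiguous segments, each with a light regime, a temperature regime, and a
# Zeitgeber-time anchor (the clock time that counts as ZT0 within the segment).
# Under cyclic light ZT0 is lights-on; under cyclic temperature it is the
# thermophase onset; constant segments carry the anchor of the regime they
# follow (subjective time).

.minute_of_day <- function(t) (as.numeric(t) / 60) %% 1440

new_protocol <- function(segments) {
  stopifnot(is.data.frame(segments))
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1) {
    gap <- as.numeric(segments$start[-1]) - as.numeric(segments$end[-nrow(segments)])
    if (any(abs(gap) > 1e-6)) stop("protocol segments must be contiguous")
  }
  if (any(segments$end <= segments$start)) stop("segment end must follow start")
  structure(list(segments = segments), class = "protocol")
}

#' Build a standard entrainment protocol
#'
#' Constructs the three-phase protocol used throughout the package: LD cycles
#' at constant 25 degC, a constant segment (LL at 25 degC before LLTC, DD at
#' 25 degC before DDTC), then 12h:12h 25 degC:16 degC temperature cycles whose
#' thermophase onset is delayed by `shift_h` hours relative to the old
#' lights-on time. Optionally, `days_free` days of constant darkness at 25 degC
#' follow the temperature cycles (free run); their subjective Zeitgeber grid is
#' projected from the temperature-cycle anchor.
#'
#' @param name `"LLTC"` (temperature cycles in constant light) or `"DDTC"`
#'   (same cycles in constant darkness).
#' @param days_ld,days_constant,days_tc number of days of each phase (>= 1).
#' @param shift_h delay, in hours within `[0, 24)`, of the thermophase onset
#'   relative to the LD lights-on time.
#' @param days_free days of constant conditions appended after the temperature
#'   cycles (default 0).
#' @param start absolute time of the first lights-on (`POSIXct`, UTC).
#' @param thermophase,cryophase temperatures (degC) of the warm and cold halves.
#' @return A `protocol` object.
#' @export
standard_protocol <- function(name = c("LLTC", "DDTC"),
                              days_ld = 2, days_constant = 3, days_tc = 6,
                              shift_h = 5, days_free = 0,
                              start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                              thermophase = 25, cryophase = 16) {
  name <- match.arg(name)
  stopifnot(days_ld >= 1, days_constant >= 1, days_tc >= 1, days_free >= 0,
            shift_h >= 0, shift_h < 24)
  lights_on <- .minute_of_day(start)
  tc_anchor <- (lights_on + shift_h * 60) %% 1440
  day <- 1440 * 60
  shift_s <- ((tc_anchor - lights_on) %% 1440) * 60
  t0 <- start
  t1 <- t0 + days_ld * day
  t2 <- t1 + days_constant * day
  # the TC segment runs until its (shifted) anchor has completed days_tc full
  # cycles, so "TC day k" exists for k = 1..days_tc
  t3 <- t2 + shift_s + days_tc * day
  t4 <- t3 + days_free * day
  const_light <- if (name == "LLTC") "on" else "off"
  seg <- data.frame(
    label = c("LD", if (name == "LLTC") "LL" else "DD", name,
              if (days_free > 0) "DD" else character(0)),
    role = c("ld", "constant", "tc", if (days_free > 0) "free" else character(0)),
    start = c(t0, t1, t2, if (days_free > 0) t3 else as.POSIXct(character(0))),
    end = c(t1, t2, t3, if (days_free > 0) t4 else as.POSIXct(character(0))),
    light_mode = c("cycle", const_light, const_light,
                   if (days_free > 0) "off" else character(0)),
    temp_mode = c("constant", "constant", "cycle",
                  if (days_free > 0) "constant" else character(0)),
    temp_level = c(thermophase, thermophase, NA,
                   if (days_free > 0) thermophase else numeric(0)),
    thermo_level = c(NA, NA, thermophase, if (days_free > 0) NA else numeric(0)),
    cryo_level = c(NA, NA, cryophase, if (days_free > 0) NA else numeric(0)),
    zt0_min = c(lights_on, lights_on, tc_anchor,
                if (days_free > 0) tc_anchor else numeric(0)),
    stringsAsFactors = FALSE
  )
  new_protocol(seg)
}

#' @export
print.protocol <- function(x, ...) {
  cat("<protocol>\n")
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  %-5s %s -- %s  light:%s temp:%s  ZT0 at %02d:%02d\n",
                s$label, format(s$start, "%Y-%m-%d %H:%M"),
                format(s$end, "%Y-%m-%d %H:%M"), s$light_mode,
                if (s$temp_mode == "cycle")
                  sprintf("%g:%g cycle", s$thermo_level, s$cryo_level)
                else sprintf("%g const", s$temp_level),
                s$zt0_min %/% 60, s$zt0_min %% 60))
  }
  invisible(x)
}

segment_index_at <- function(protocol, t) {
  s <- protocol$segments
  i <- findInterval(as.numeric(t), as.numeric(s$start))
  bad <- i == 0 | t >= s$end[nrow(s)]
  if (any(bad)) {
    stop("time ", format(t[bad][1], "%Y-%m-%d %H:%M", tz = "UTC"),
         " is outside the protocol span")
  }
  i
}

#' Zeitgeber time of an absolute time point
#'
#' Minutes elapsed since the most recent ZT0 anchor of the protocol segment
#' containing `t`. Within a segment the result is periodic with period 1440.
#'
#' @param t `POSIXct` time(s) inside the protocol span.
#' @param protocol a [standard_protocol()] (or any `protocol`).
#' @return Numeric vector of ZT minutes in `[0, 1440)`.
#' @export
zt_of <- function(t, protocol) {
  i <- segment_index_at(protocol, t)
  (.minute_of_day(t) - protocol$segments$zt0_min[i]) %% 1440
}

#' Light and temperature at an absolute time point
#'
#' Evaluates the segment's square waves at `t`. Under cyclic light, lights are
#' on for ZT in `[0, 720)`; under cyclic temperature the thermophase spans ZT
#' `[0, 720)`.
#'
#' @inheritParams zt_of
#' @return A data frame with columns `light` (`"on"`/`"off"`) and `temp` (degC).
#' @export
environment_at <- function(t, protocol) {
  i <- segment_index_at(protocol, t)
  s <- protocol$segments
  zt <- (.minute_of_day(t) - s$zt0_min[i]) %% 1440
  light <- ifelse(s$light_mode[i] == "cycle",
                  ifelse(zt < 720, "on", "off"), s$light_mode[i])
  temp <- ifelse(s$temp_mode[i] == "cycle",
                 ifelse(zt < 720, s$thermo_level[i], s$cryo_level[i]),
                 s$temp_level[i])
  data.frame(light = light, temp = temp)
}

#' Enumerate the full Zeitgeber days of a protocol
#'
#' A "day" is a full ZT0-to-ZT0 span (1440 min) lying entirely inside one
#' segment; partial handover days between regimes are not counted, so e.g.
#' "TC day 6" means the 6th full temperature-cycle day.
#'
#' @param protocol a `protocol`.
#' @return Data frame with columns `label` (e.g. `"LLTC3"`), `role`
#'   (`ld`/`constant`/`tc`/`free`), `index` (day number within the segment),
#'   `start`, `end` (`POSIXct`).
#' @export
protocol_days <- function(protocol) {
  out <- list()
  for (i in seq_len(nrow(protocol$segments))) {
    s <- protocol$segments[i, ]
    off <- (s$zt0_min - .minute_of_day(s$start)) %% 1440
    t_a <- s$start + off * 60
    k <- 0L
    while (as.numeric(t_a) + 1440 * 60 <= as.numeric(s$end) + 1e-6) {
      k <- k + 1L
      out[[length(out) + 1L]] <- data.frame(
        label = paste0(s$label, k), role = s$role, index = k,
        start = t_a, end = t_a + 1440 * 60, stringsAsFactors = FALSE)
      t_a <- t_a + 1440 * 60
    }
  }
  do.call(rbind, out)
}

#' Zeitgeber transitions of one protocol day
#'
#' The environmental transitions of a day, as ZT minutes: lights-on/off for a
#' light-cycled day, warm-onset/cold-onset for a temperature-cycled day, none
#' for constant days. These are the landmarks anticipation windows end at.
#'
#' @param protocol a `protocol`.
#' @param day a day label as produced by [protocol_days()] (e.g. `"LD2"`,
#'   `"LLTC6"`), or a single row of that data frame.
#' @return Data frame with columns `zt` (minutes) and `kind`.
#' @export
zt_transitions <- function(protocol, day) {
  days <- protocol_days(protocol)
  if (is.character(day)) {
    row <- days[days$label == day, ]
    if (nrow(row) != 1) stop("unknown protocol day '", day, "'")
  } else {
    row <- day
  }
  s <- protocol$segments[protocol$segments$label == sub("[0-9]+$", "", row$label) &
                           protocol$segments$role == row$role, ]
  if (s$light_mode == "cycle") {
    data.frame(zt = c(0, 720), kind = c("lights-on", "lights-off"))
  } else if (s$temp_mode == "cycle") {
    data.frame(zt = c(0, 720), kind = c("warm-onset", "cold-onset"))
  } else {
    data.frame(zt = numeric(0), kind = character(0))
  }
}

# Absolute times of every environmental transition in the protocol (used for
# startle impulses in the simulator and for figure shading).
transition_times <- function(protocol) {
  out <- list()
  for (i in seq_len(nrow(protocol$segments))) {
    s <- protocol$segments[i, ]
    if (s$light_mode != "cycle" && s$temp_mode != "cycle") next
    kinds <- if (s$light_mode == "cycle") c("lights-on", "lights-off")
             else c("warm-onset", "cold-onset")
    for (half in c(0, 720)) {
      off <- ((s$zt0_min + half) - .minute_of_day(s$start)) %% 1440
      tt <- seq(s$start + off * 60, s$end - 1, by = 1440 * 60)
      tt <- tt[tt < s$end]
      if (length(tt) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          time = tt, kind = kinds[1 + half / 720], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(time = as.POSIXct(character(0)), kind = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$time), , drop = FALSE]
}
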