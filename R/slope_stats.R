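#' Slope of the line between two activity time points
#'
#' The elementary statistic everything else builds on: the derivative of the
#' straight line between activity at two Zeitgeber times,
#' `(act_to - act_from) / (t_to - t_from)`, with time in minutes and activity
#' in percent of the fly's (or the median's) maximum.
#'
#' @param act_from,act_to activity values at the two landmarks.
#' @param t_from,t_to landmark times in ZT minutes (`t_to != t_from`).
#' @return Slope in (percent of max) per minute.
#' @export
slope_between <- function(act_from, act_to, t_from, t_to) {
  if (any(t_to == t_from)) stop("landmark times must differ")
  (act_to - act_from) / (t_to - t_from)
}

#' Locate the anticipation landmarks on a median profile
#'
#' Finds the two population-level landmarks of the anticipatory activity
#' increase preceding a Zeitgeber transition: `zt_min`, the *last* bin
#' attaining the window's minimum median activity, and `zt_max`, the *first*
#' bin after `zt_min` attaining the maximum median activity before the
#' transition. The bin containing the transition itself (and, with
#' `exclude_bins > 1`, further bins before it) is excluded so the acute startle
#' response to the transition cannot masquerade as anticipation. Manual
#' landmark overrides are accepted and recorded as provenance.
#'
#' @param profile a [median_profile()] with a ZT grid.
#' @param transition_zt ZT minute of the Zeitgeber transition the window ends
#'   at (e.g. 720 for lights-off or cold-onset).
#' @param window_start_zt ZT minute the search window starts at (default: 6 h
#'   before the transition).
#' @param exclude_bins number of bins at/just before the transition excluded
#'   from the search (default 1: the transition bin itself).
#' @param zt_min,zt_max optional manual overrides (ZT minutes of existing
#'   bins); recorded with `manual = TRUE`.
#' @return List of class `landmarks`: `zt_min`, `zt_max`, `act_at_min`,
#'   `act_at_max`, `manual`.
#' @export
detect_landmarks <- function(profile, transition_zt,
                             window_start_zt = transition_zt - 360,
                             exclude_bins = 1, zt_min = NULL, zt_max = NULL) {
  stopifnot(inherits(profile, "population_profile"))
  zt <- profile$zt
  med <- profile$median_value
  if (!is.null(zt_min) && !is.null(zt_max)) {
    i <- match(zt_min, zt); j <- match(zt_max, zt)
    if (is.na(i) || is.na(j)) stop("manual landmark is not an existing bin")
    return(structure(list(zt_min = zt_min, zt_max = zt_max,
                          act_at_min = med[i], act_at_max = med[j],
                          manual = TRUE), class = "landmarks"))
  }
  last_allowed <- transition_zt - exclude_bins * profile$bin_minutes
  cand <- which(zt >= window_start_zt & zt <= last_allowed & !is.na(med))
  if (length(cand) < 3) stop("search window must contain at least 3 bins")
  if (diff(range(med[cand])) == 0) {
    stop("no anticipation structure: median profile is flat in the window")
  }
  i_min <- cand[max(which(med[cand] == min(med[cand])))]
  after <- cand[cand > i_min]
  if (length(after) == 0 || all(med[after] == med[i_min])) {
    stop("no anticipation structure: no rise after the minimum; ",
         "try a narrower or earlier window")
  }
  i_max <- after[min(which(med[after] == max(med[after])))]
  structure(list(zt_min = zt[i_min], zt_max = zt[i_max],
                 act_at_min = med[i_min], act_at_max = med[i_max],
                 manual = FALSE), class = "landmarks")
}

#' Per-fly anticipation slopes at shared landmarks
#'
#' Applies the slope formula to every fly's own normalized activity between
#' the population-level landmarks (landmarks are shared across flies by
#' design; negative slopes are legal and feed the classifier). Flies missing
#' data at either landmark are excluded and reported.
#'
#' @param norm a day's [normalize_activity()] values with ZT grid.
#' @param zt_min,zt_max landmark ZT minutes (bins of `norm`).
#' @return List with `slopes` (named numeric, one per usable fly) and
#'   `excluded` (fly ids with missing landmark bins).
#' @export
fly_slopes <- function(norm, zt_min, zt_max) {
  stopifnot(inherits(norm, "normalized_activity"))
  i <- match(zt_min, norm$zt); j <- match(zt_max, norm$zt)
  if (is.na(i) || is.na(j)) stop("landmarks must be existing bins")
  a_min <- norm$values[i, ]; a_max <- norm$values[j, ]
  ok <- !is.na(a_min) & !is.na(a_max)
  slopes <- slope_between(a_min[ok], a_max[ok], zt_min, zt_max)
  names(slopes) <- norm$fly_ids[ok]
  list(slopes = slopes, excluded = norm$fly_ids[!ok])
}

#' Theoretical slope: the slope of the population median
#'
#' @param profile a [median_profile()].
#' @param zt_min,zt_max landmark ZT minutes.
#' @return Slope of the median profile between the landmarks.
#' @export
slo_the <- function(profile, zt_min, zt_max) {
  stopifnot(inherits(profile, "population_profile"))
  i <- match(zt_min, profile$zt); j <- match(zt_max, profile$zt)
  if (is.na(i) || is.na(j)) stop("landmarks must be existing bins")
  slope_between(profile$median_value[i], profile$median_value[j], zt_min, zt_max)
}

#' Experimental slope: the median of the per-fly slopes
#'
#' @param slopes numeric vector of per-fly slopes.
#' @return Their median.
#' @export
slo_exp <- function(slopes) {
  if (length(slopes) == 0) stop("no fly slopes")
  stats::median(slopes)
}

#' Population synchronization ratio Slo_exp / Slo_the
#'
#' Close to 1 when most individuals behave like the population median
#' (synchronized populations); well below 1 when many individuals deviate from
#' the median (desynchronized populations).
#'
#' @param slo_exp median of the per-fly slopes.
#' @param slo_the slope of the median profile; must be positive in uphill mode
#'   and negative in downhill mode.
#' @param direction `"uphill"` (anticipatory increase, the default) or
#'   `"downhill"` (post-peak decrease on free-running days).
#' @return `slo_exp / slo_the`.
#' @export
sync_ratio <- function(slo_exp, slo_the, direction = c("uphill", "downhill")) {
  direction <- match.arg(direction)
  if (direction == "uphill" && slo_the <= 0) {
    stop("theoretical slope non-positive; ratio undefined")
  }
  if (direction == "downhill" && slo_the >= 0) {
    stop("theoretical slope non-negative; downhill ratio undefined")
  }
  slo_exp / slo_the
}

#' Classify flies as anticipating or non-anticipating
#'
#' A fly anticipates the transition when its individual slope exceeds half the
#' theoretical slope (`slope > 0.5 * slo_the`); in downhill mode a fly
#' "anticipates" when it decreases its activity steeper than half the
#' theoretical slope (`slope < 0.5 * slo_the`, both negative).
#'
#' @param slopes named per-fly slopes.
#' @param slo_the the theoretical slope.
#' @param direction `"uphill"` or `"downhill"`.
#' @return List with `anticipating` (named logical) and `fraction` (percent of
#'   flies anticipating).
#' @export
classify_anticipation <- function(slopes, slo_the,
                                  direction = c("uphill", "downhill")) {
  direction <- match.arg(direction)
  flag <- if (direction == "uphill") slopes > 0.5 * slo_the
          else slopes < 0.5 * slo_the
  list(anticipating = flag, fraction = 100 * sum(flag) / length(flag))
}

.make_slope_analysis <- function(norm, profile, lm, direction) {
  fs <- fly_slopes(norm, lm$zt_min, lm$zt_max)
  s_the <- slo_the(profile, lm$zt_min, lm$zt_max)
  s_exp <- slo_exp(fs$slopes)
  cls <- classify_anticipation(fs$slopes, s_the, direction)
  structure(
    list(landmarks = lm, fly_slopes = fs$slopes, excluded_flies = fs$excluded,
         slo_the = s_the, slo_exp = s_exp,
         ratio = sync_ratio(s_exp, s_the, direction),
         anticipating = cls$anticipating,
         fraction_anticipating = cls$fraction,
         n_flies = length(fs$slopes), direction = direction),
    class = "slope_analysis"
  )
}

#' Full anticipation-slope analysis of one day
#'
#' Detects the landmarks on the population median profile (unless supplied),
#' computes the per-fly slopes between them, the theoretical slope `Slo_the`
#' (slope of the median), the experimental slope `Slo_exp` (median of the
#' per-fly slopes), their ratio as the population-synchronization index, and
#' the half-threshold anticipation classification.
#'
#' @param norm a day's normalized activity (see [daily_profile()]).
#' @param profile the matching [median_profile()].
#' @param transition_zt ZT minute of the Zeitgeber transition.
#' @param window_start_zt start of the landmark search window (default 6 h
#'   before the transition).
#' @param zt_min,zt_max optional manual landmark overrides.
#' @param exclude_bins bins excluded at the transition, see
#'   [detect_landmarks()].
#' @return An object of class `slope_analysis`.
#' @export
analyze_slopes <- function(norm, profile, transition_zt,
                           window_start_zt = transition_zt - 360,
                           zt_min = NULL, zt_max = NULL, exclude_bins = 1) {
  lm <- detect_landmarks(profile, transition_zt, window_start_zt,
                         exclude_bins, zt_min = zt_min, zt_max = zt_max)
  .make_slope_analysis(norm, profile, lm, "uphill")
}

#' Downhill slope analysis for free-running days
#'
#' Mirror of [analyze_slopes()] for the activity *decrease* after the
#' (subjective) morning peak on a free-running day: `zt_max` is the first bin
#' attaining the window's maximum median, `zt_min` the last bin attaining the
#' subsequent minimum; slopes are negative, and a fly counts as synchronized
#' when it decreases its locomotion steeper than half the theoretical slope.
#'
#' @param norm,profile as in [analyze_slopes()].
#' @param window_zt two ZT minutes delimiting the (subjective-day) search
#'   window, default `c(0, 720)`.
#' @param zt_min,zt_max optional manual overrides.
#' @return An object of class `slope_analysis` with `direction = "downhill"`.
#' @export
analyze_downhill <- function(norm, profile, window_zt = c(0, 720),
                             zt_min = NULL, zt_max = NULL) {
  stopifnot(inherits(profile, "population_profile"), length(window_zt) == 2)
  zt <- profile$zt
  med <- profile$median_value
  if (is.null(zt_min) != is.null(zt_max)) {
    stop("override both landmarks or neither")
  }
  if (!is.null(zt_min)) {
    i <- match(zt_min, zt); j <- match(zt_max, zt)
    if (is.na(i) || is.na(j)) stop("manual landmark is not an existing bin")
    lm <- structure(list(zt_min = zt_min, zt_max = zt_max,
                         act_at_min = med[i], act_at_max = med[j],
                         manual = TRUE), class = "landmarks")
    return(.make_slope_analysis(norm, profile, lm, "downhill"))
  }
  cand <- which(zt >= window_zt[1] & zt < window_zt[2] & !is.na(med))
  if (length(cand) < 3) stop("search window must contain at least 3 bins")
  if (diff(range(med[cand])) == 0) {
    stop("no anticipation structure: median profile is flat in the window")
  }
  i_max <- cand[min(which(med[cand] == max(med[cand])))]
  after <- cand[cand > i_max]
  if (length(after) == 0 || all(med[after] == med[i_max])) {
    stop("no anticipation structure: no decline after the peak")
  }
  i_min <- after[max(which(med[after] == min(med[after])))]
  lm <- structure(list(zt_min = zt[i_min], zt_max = zt[i_max],
                       act_at_min = med[i_min], act_at_max = med[i_max],
                       manual = FALSE), class = "landmarks")
  .make_slope_analysis(norm, profile, lm, "downhill")
}

#' @export
print.slope_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("<slope_analysis> (%s) n = %d flies\n",
           "  landmarks: ZT_min %.1f h (act %.1f), ZT_max %.1f h (act %.1f)%s\n",
           "  Slo_the = %.2f, Slo_exp = %.2f, ratio = %.2f\n",
           "  anticipating: %.1f%%\n"),
    x$direction, x$n_flies,
    x$landmarks$zt_min / 60, x$landmarks$act_at_min,
    x$landmarks$zt_max / 60, x$landmarks$act_at_max,
    if (x$landmarks$manual) " [manual]" else "",
    x$slo_the, x$slo_exp, x$ratio, x$fraction_anticipating))
  if (length(x$excluded_flies) > 0) {
    cat("  excluded (missing landmark bins):",
        paste(x$excluded_flies, collapse = ", "), "\n")
  }
  invisible(x)
}
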