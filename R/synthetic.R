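# Labeled inhomogeneous-Poisson generator of per-minute fly activity under any
# protocol. Each fly's rate (counts/min) is
#   lambda(t) = baseline * siesta(zt) + morning_ramp(zt) + evening_ramp(zt)
#               + startle(t)
# with piecewise-linear crepuscular ramps, an exponentially decaying startle
# impulse at every Zeitgeber transition, and a multiplicative mid-day siesta
# trough. In constant segments the phase advances at the free-running period.
# Phenotype classes: "sync" (intact anticipation), "desync" (evening ramp
# onset re-drawn uniformly over the cycle), "flat" (no anticipation ramps).

#' Configuration of a synthetic fly population
#'
#' All rates are counts per minute; all times are ZT minutes. The defaults
#' describe a synchronized control population entrained to a 12h:12h cycle:
#' an evening anticipation ramp from ZT 510 to ZT 690 (i.e. ZT 8.5-11.5,
#' the landmark range of control genotypes), a weaker morning ramp before
#' (subjective) lights-on, a mid-day siesta, and a startle burst at every
#' environmental transition.
#'
#' @param n_flies population size.
#' @param baseline_rate baseline activity (counts/min).
#' @param evening,morning anticipatory ramps: lists with `amplitude`
#'   (counts/min at the peak), `onset_zt`, `peak_zt` (ZT minutes; the ramp
#'   rises linearly onset to peak, then decays linearly over `fall_min`).
#' @param startle list with `amplitude` (counts/min at the transition) and
#'   `half_life_min` of the exponential decay.
#' @param siesta_depth multiplicative reduction of the baseline during the
#'   siesta (0 = none, 1 = complete rest).
#' @param siesta_zt two ZT minutes delimiting the siesta trough.
#' @param p_desync fraction of flies whose evening ramp onset is re-drawn
#'   uniformly over the cycle (clock-desynchronized phenotype).
#' @param p_flat fraction of flies without any anticipation ramp
#'   (clock-disrupted phenotype); `p_desync + p_flat <= 1`. Disrupted flies
#'   show unconsolidated tonic activity at a fly-specific level drawn
#'   uniformly from `tonic_range`, emulating the elevated cryophase activity
#'   of clock-disrupted genotypes; they have no siesta and no ramps.
#' @param tonic_range two rates (counts/min) bounding the uniform per-fly
#'   tonic activity level of flat (clock-disrupted) flies.
#' @param phase_delay_min population-wide delay of both ramps (minutes).
#' @param freerun_period_min endogenous period used in constant segments.
#' @param fall_min minutes over which a ramp decays back to zero after its peak.
#' @param overdispersion extra-Poisson noise: per-fly gamma rate multiplier
#'   with variance `overdispersion` (0 = plain Poisson, the default).
#' @param seed integer RNG seed; a fixed seed makes the population
#'   bit-reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_flies = 60, baseline_rate = 0.25,
                       evening = list(amplitude = 2, onset_zt = 510, peak_zt = 690),
                       morning = list(amplitude = 1, onset_zt = 1320, peak_zt = 1430),
                       startle = list(amplitude = 3, half_life_min = 10),
                       siesta_depth = 0.5, siesta_zt = c(270, 510),
                       p_desync = 0, p_flat = 0, tonic_range = c(0.2, 6),
                       phase_delay_min = 0,
                       freerun_period_min = 1440, fall_min = 120,
                       overdispersion = 0, seed = 1) {
  cfg <- list(n_flies = as.integer(n_flies), baseline_rate = baseline_rate,
              evening = evening, morning = morning, startle = startle,
              siesta_depth = siesta_depth, siesta_zt = siesta_zt,
              p_desync = p_desync, p_flat = p_flat, tonic_range = tonic_range,
              phase_delay_min = phase_delay_min,
              freerun_period_min = freerun_period_min, fall_min = fall_min,
              overdispersion = overdispersion, seed = as.integer(seed))
  stopifnot(cfg$n_flies >= 1, cfg$baseline_rate >= 0,
            cfg$evening$amplitude >= 0, cfg$morning$amplitude >= 0,
            cfg$startle$amplitude >= 0, cfg$startle$half_life_min > 0,
            cfg$siesta_depth >= 0, cfg$siesta_depth <= 1,
            cfg$p_desync >= 0, cfg$p_flat >= 0,
            cfg$p_desync + cfg$p_flat <= 1,
            length(cfg$tonic_range) == 2, all(cfg$tonic_range >= 0),
            cfg$tonic_range[2] >= cfg$tonic_range[1],
            cfg$freerun_period_min > 0, cfg$fall_min > 0,
            cfg$overdispersion >= 0)
  structure(cfg, class = "sim_config")
}

#' Preset population configurations
#'
#' Named configurations emulating the qualitative phenotype classes seen in
#' temperature-cycle entrainment experiments:
#' \describe{
#'   \item{control_LLTC}{fully synchronized controls; evening peak in the late
#'     thermophase, just before the cold onset.}
#'   \item{cycDN_like}{clock-disrupted population: half the flies lose their
#'     evening anticipation and show unconsolidated tonic activity instead,
#'     emulating dominant-negative clock disruption (reduced synchronization
#'     ratio, roughly half the flies anticipating).}
#'   \item{delayed_EO}{synchronized but with both ramps delayed by 2 h.}
#'   \item{control_DDTC}{morning-dominant controls of dark temperature
#'     cycles: main peak in the first half of the thermophase.}
#'   \item{arrhythmic}{no anticipation in any fly.}
#' }
#'
#' @param name preset name.
#' @param n_flies population size (default 60).
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("control_LLTC", "cycDN_like", "delayed_EO",
                                "control_DDTC", "arrhythmic"),
                       n_flies = 60, seed = 1) {
  name <- match.arg(name)
  switch(name,
    control_LLTC = sim_config(n_flies = n_flies, seed = seed),
    cycDN_like = sim_config(n_flies = n_flies, seed = seed, p_flat = 0.5),
    delayed_EO = sim_config(n_flies = n_flies, seed = seed,
                            phase_delay_min = 120),
    control_DDTC = sim_config(
      n_flies = n_flies, seed = seed,
      morning = list(amplitude = 2, onset_zt = 1320, peak_zt = 90),
      evening = list(amplitude = 0.6, onset_zt = 510, peak_zt = 690)),
    arrhythmic = sim_config(n_flies = n_flies, seed = seed, p_flat = 1)
  )
}

# Piecewise-linear circular ramp: 0 at onset, amplitude at peak, back to 0
# over `fall` minutes; phase in [0, 1440).
ramp_value <- function(phase, onset, peak, amplitude, fall) {
  rise <- (peak - onset) %% 1440
  if (rise == 0) rise <- 1440
  d <- (phase - onset) %% 1440
  up <- d <= rise
  down <- !up & (d - rise) < fall
  amplitude * (up * d / rise + down * pmax(0, 1 - (d - rise) / fall))
}

# Phase (subjective ZT, minutes) for every minute of the protocol; cyclic
# segments follow zt_of, constant segments advance at the free-running period
# starting from the phase the carried anchor implies at segment entry.
.sim_phase <- function(timestamps, protocol, freerun) {
  phase <- numeric(length(timestamps))
  segs <- protocol$segments
  tnum <- as.numeric(timestamps)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    in_seg <- tnum >= as.numeric(s$start) & tnum < as.numeric(s$end)
    if (!any(in_seg)) next
    if (s$light_mode == "cycle" || s$temp_mode == "cycle") {
      phase[in_seg] <- (.minute_of_day(timestamps[in_seg]) - s$zt0_min) %% 1440
    } else {
      phase0 <- (.minute_of_day(s$start) - s$zt0_min) %% 1440
      el <- (tnum[in_seg] - as.numeric(s$start)) / 60
      phase[in_seg] <- (phase0 + el * 1440 / freerun) %% 1440
    }
  }
  phase
}

#' Simulate a labeled fly population under a protocol
#'
#' Draws per-minute Poisson counts for `cfg$n_flies` flies over the full span
#' of `protocol`, with ground-truth phenotype labels. Given the same `cfg`
#' (including its seed) and protocol the output is bit-reproducible.
#'
#' @param cfg a [sim_config()].
#' @param protocol a [standard_protocol()] (or any `protocol`).
#' @param keep_rates keep the underlying per-fly rate functions (minutes x
#'   flies matrix) in the result, for diagnostics and tests.
#' @return List with `matrix` (an [activity_matrix()]), `labels` (data frame:
#'   `fly_id`, `class` in sync/desync/flat, `evening_onset_zt`,
#'   `evening_peak_zt`), and optionally `rates`.
#' @export
simulate_population <- function(cfg, protocol, keep_rates = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(protocol, "protocol"))
  set.seed(cfg$seed)
  segs <- protocol$segments
  t0 <- segs$start[1]
  t_end <- segs$end[nrow(segs)]
  ts <- seq(t0, t_end - 60, by = 60)
  n_min <- length(ts)
  n <- cfg$n_flies

  phase <- .sim_phase(ts, protocol, cfg$freerun_period_min)

  # shared components
  siesta <- ifelse(phase >= cfg$siesta_zt[1] & phase < cfg$siesta_zt[2],
                   1 - cfg$siesta_depth, 1)
  base <- cfg$baseline_rate * siesta
  startle <- numeric(n_min)
  if (cfg$startle$amplitude > 0) {
    tr <- transition_times(protocol)
    tnum <- as.numeric(ts)
    hl <- cfg$startle$half_life_min
    for (tt in as.numeric(tr$time)) {
      idx <- which(tnum >= tt & tnum < tt + 8 * hl * 60)
      if (length(idx) > 0) {
        startle[idx] <- startle[idx] +
          cfg$startle$amplitude * 2^(-(tnum[idx] - tt) / 60 / hl)
      }
    }
  }
  morning <- ramp_value(phase,
                        (cfg$morning$onset_zt + cfg$phase_delay_min) %% 1440,
                        (cfg$morning$peak_zt + cfg$phase_delay_min) %% 1440,
                        cfg$morning$amplitude, cfg$fall_min)
  ev_onset_sync <- (cfg$evening$onset_zt + cfg$phase_delay_min) %% 1440
  ev_peak_sync <- (cfg$evening$peak_zt + cfg$phase_delay_min) %% 1440
  ev_len <- (cfg$evening$peak_zt - cfg$evening$onset_zt) %% 1440
  evening_sync <- ramp_value(phase, ev_onset_sync, ev_peak_sync,
                             cfg$evening$amplitude, cfg$fall_min)

  # phenotype classes with exact counts
  n_desync <- round(cfg$p_desync * n)
  n_flat <- round(cfg$p_flat * n)
  if (n_desync + n_flat > n) n_flat <- n - n_desync
  classes <- sample(rep(c("desync", "flat", "sync"),
                        c(n_desync, n_flat, n - n_desync - n_flat)))
  onsets <- ifelse(classes == "sync", ev_onset_sync, NA_real_)
  onsets[classes == "desync"] <- stats::runif(n_desync, 0, 1440)
  peaks <- (onsets + ev_len) %% 1440
  tonic <- rep(NA_real_, n)
  tonic[classes == "flat"] <- stats::runif(n_flat, cfg$tonic_range[1],
                                           cfg$tonic_range[2])

  mult <- if (cfg$overdispersion > 0) {
    stats::rgamma(n, shape = 1 / cfg$overdispersion,
                  scale = cfg$overdispersion)
  } else rep(1, n)

  counts <- matrix(0L, n_min, n)
  rates <- if (keep_rates) matrix(0, n_min, n) else NULL
  shared <- base + startle
  for (i in seq_len(n)) {
    # flat flies: unconsolidated tonic activity (no clock output at all);
    # others: entrained baseline/siesta plus the anticipation ramps
    lam <- if (classes[i] == "flat") tonic[i] + startle else {
      shared + morning +
        if (classes[i] == "sync") evening_sync
        else ramp_value(phase, onsets[i], peaks[i], cfg$evening$amplitude,
                        cfg$fall_min)
    }
    lam <- lam * mult[i]
    counts[, i] <- stats::rpois(n_min, lam)
    if (keep_rates) rates[, i] <- lam
  }

  fly_ids <- sprintf("fly_%03d", seq_len(n))
  labels <- data.frame(fly_id = fly_ids, class = classes,
                       evening_onset_zt = onsets, evening_peak_zt = peaks,
                       tonic_rate = tonic, stringsAsFactors = FALSE)
  out <- list(matrix = activity_matrix(ts, counts, fly_ids = fly_ids),
              labels = labels)
  if (keep_rates) out$rates <- rates
  out
}
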