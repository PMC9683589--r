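# Small builders shared across test files. Everything is generated in code;
# no fixture files.

ts_at <- function(start = "2024-01-01 08:00:00", n = 10, by_min = 1) {
  seq(as.POSIXct(start, tz = "UTC"), by = by_min * 60, length.out = n)
}

toy_matrix <- function(counts, start = "2024-01-01 08:00:00", ...) {
  counts <- as.matrix(counts)
  activity_matrix(ts_at(start, nrow(counts)), counts, ...)
}

# a normalized_activity object built directly from a values matrix (bins x
# flies) on a ZT grid, bypassing the binning path
make_norm <- function(values, zt = (seq_len(nrow(as.matrix(values))) - 1) * 30,
                      bin_minutes = 30) {
  values <- as.matrix(values)
  structure(
    list(bin_start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + zt * 60,
         zt = zt, values = values,
         fly_ids = sprintf("fly_%03d", seq_len(ncol(values))),
         bin_minutes = bin_minutes, excluded = character(0)),
    class = "normalized_activity")
}

make_profile <- function(median_value,
                         zt = (seq_along(median_value) - 1) * 30,
                         bin_minutes = 30) {
  structure(
    list(zt = zt,
         bin_start = as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + zt * 60,
         median_value = median_value,
         n_flies = rep(1L, length(median_value)), bin_minutes = bin_minutes),
    class = "population_profile")
}

lltc_protocol <- function(...) standard_protocol("LLTC", 2, 3, 6, 5, ...)

# shared DAM2 line writer for reader tests
dam_line <- function(i, date, time, status = 1, counts = rep(0, 32)) {
  paste(c(i, date, time, status, rep(0, 6), counts), collapse = "\t")
}

# end-to-end pipeline statistic for simulation-based tests
sim_slope_analysis <- function(cfg, protocol = lltc_protocol(), day = "TC6",
                               transition_zt = 720) {
  sim <- simulate_population(cfg, protocol)
  prep <- daily_profile(sim$matrix, protocol, day)
  list(analysis = analyze_slopes(prep$norm, prep$profile,
                                 transition_zt = transition_zt),
       prep = prep, sim = sim)
}
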