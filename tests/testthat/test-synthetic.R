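test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_desync = 0.6, p_flat = 0.6))
  expect_error(sim_config(baseline_rate = -1))
  expect_error(sim_config(tonic_range = c(3, 1)))
  expect_s3_class(sim_preset("cycDN_like"), "sim_config")
})

test_that("a fixed seed makes the population bit-reproducible", {
  p <- standard_protocol("LLTC", days_ld = 1, days_constant = 1, days_tc = 1)
  a <- simulate_population(sim_config(n_flies = 8, seed = 99, p_desync = 0.25,
                                      p_flat = 0.25), p)
  b <- simulate_population(sim_config(n_flies = 8, seed = 99, p_desync = 0.25,
                                      p_flat = 0.25), p)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$labels, b$labels)
  c <- simulate_population(sim_config(n_flies = 8, seed = 100), p)
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("empirical bin means match the rate function within 3 standard errors", {
  p <- standard_protocol("LLTC", days_ld = 1, days_constant = 1, days_tc = 2)
  sim <- simulate_population(sim_config(n_flies = 200, seed = 21), p,
                             keep_rates = TRUE)
  b <- bin_counts(sim$matrix, 30)
  # integrate the (shared, all-sync) rate over each bin
  lam_bin <- rowsum(sim$rates[, 1], rep(seq_len(nrow(b$counts)), each = 30)[
    seq_len(nrow(sim$rates))])[, 1]
  emp <- rowMeans(b$counts)
  z <- (emp - lam_bin) / sqrt(lam_bin / 200)
  expect_gt(mean(abs(z) <= 3), 0.99)
  expect_lt(max(abs(z)), 5)
})

test_that("flat flies carry no anticipation-ramp contribution", {
  p <- standard_protocol("LLTC", days_ld = 1, days_constant = 1, days_tc = 1)
  sim <- simulate_population(sim_config(n_flies = 20, seed = 13, p_flat = 0.5,
                                        tonic_range = c(1, 1)), p,
                             keep_rates = TRUE)
  flat <- which(sim$labels$class == "flat")
  # identical tonic level: all flat flies share one rate function...
  for (i in flat[-1]) expect_equal(sim$rates[, i], sim$rates[, flat[1]])
  # ...which is constant outside the startle windows (no ramps, no siesta)
  sync <- which(sim$labels$class == "sync")[1]
  no_startle <- sim$rates[, flat[1]] == min(sim$rates[, flat[1]])
  expect_equal(unique(sim$rates[no_startle, flat[1]]), 1)
  expect_gt(max(sim$rates[, sync]) , max(sim$rates[no_startle, flat[1]]))
})

test_that("class counts are exact for the requested fractions", {
  p <- standard_protocol("LLTC", days_ld = 1, days_constant = 1, days_tc = 1)
  sim <- simulate_population(sim_config(n_flies = 60, seed = 2,
                                        p_desync = 0.2, p_flat = 0.3), p)
  expect_equal(as.vector(table(sim$labels$class)[c("desync", "flat", "sync")]),
               c(12L, 18L, 30L))
  expect_true(all(is.na(sim$labels$evening_onset_zt[sim$labels$class == "flat"])))
  expect_true(all(!is.na(sim$labels$tonic_rate[sim$labels$class == "flat"])))
})

test_that("presets produce their characteristic activity phases", {
  p <- lltc_protocol()
  ctrl <- sim_slope_analysis(sim_preset("control_LLTC", n_flies = 30, seed = 31))
  # anticipatory peak (startle bins at the transitions aside) in the late
  # thermophase, just before the cold onset
  in_thermo <- which(ctrl$prep$profile$zt >= 30 & ctrl$prep$profile$zt <= 690)
  peak_zt <- ctrl$prep$profile$zt[in_thermo][
    which.max(ctrl$prep$profile$median_value[in_thermo])]
  expect_true(peak_zt >= 600 && peak_zt <= 690)

  pd <- standard_protocol("DDTC", 2, 3, 6, 5)
  simd <- simulate_population(sim_preset("control_DDTC", n_flies = 30,
                                         seed = 32), pd)
  prepd <- daily_profile(simd$matrix, pd, "TC6")
  peak_d <- prepd$profile$zt[which.max(prepd$profile$median_value)]
  expect_lt(peak_d, 360)  # first half of the warm phase

  # a 2-h population-wide delay empties the late thermophase and moves the
  # anticipatory activity into the early cryophase
  del <- sim_slope_analysis(sim_preset("delayed_EO", n_flies = 30, seed = 33))
  at <- function(prep, zt) prep$profile$median_value[prep$profile$zt == zt]
  expect_gt(at(ctrl$prep, 630), at(del$prep, 630) + 10)
  expect_gt(at(del$prep, 810), at(ctrl$prep, 810) + 10)
})

test_that("an all-arrhythmic population has no anticipation slope left", {
  ctrl <- sim_slope_analysis(sim_preset("control_LLTC", n_flies = 30,
                                        seed = 41))
  out <- tryCatch(
    sim_slope_analysis(sim_preset("arrhythmic", n_flies = 30, seed = 41)),
    error = function(e) {
      expect_match(conditionMessage(e), "anticipation")
      NULL
    })
  if (!is.null(out)) {
    # whatever residual structure noise produces, the slopes have collapsed
    expect_lt(abs(out$analysis$slo_exp), 0.3 * ctrl$analysis$slo_exp)
    expect_lt(out$analysis$slo_the, 0.3 * ctrl$analysis$slo_the)
  }
})

test_that("free-running phase follows freerun_period_min in constant segments", {
  p <- standard_protocol("DDTC", days_ld = 1, days_constant = 1, days_tc = 2,
                         shift_h = 0, days_free = 2)
  # a 23-h free-runner should peak ~2 h earlier on DD2 than a 24-h one
  f24 <- simulate_population(sim_config(n_flies = 40, seed = 51,
                                        startle = list(amplitude = 0,
                                                       half_life_min = 10)), p)
  f23 <- simulate_population(sim_config(n_flies = 40, seed = 51,
                                        freerun_period_min = 1380,
                                        startle = list(amplitude = 0,
                                                       half_life_min = 10)), p)
  peak_of <- function(sim) {
    prep <- daily_profile(sim$matrix, p, "DD2")
    prep$profile$zt[which.max(prep$profile$median_value)]
  }
  expect_lt(peak_of(f23), peak_of(f24))
})
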