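test_that("landmark tie rules: last minimum, first maximum, startle excluded", {
  # transition right after the 5th bin; the 6th bin is the startle bin
  pr <- make_profile(c(10, 5, 5, 20, 40, 95), zt = seq(0, 150, 30))
  lm <- detect_landmarks(pr, transition_zt = 150, window_start_zt = 0)
  expect_equal(lm$zt_min, 60)   # last of the tied minima (bin 3)
  expect_equal(lm$zt_max, 120)  # bin 5; the startle bin at 150 is excluded
  expect_equal(lm$act_at_min, 5)
  expect_equal(lm$act_at_max, 40)
  expect_false(lm$manual)
})

test_that("monotone profiles and overrides behave as documented", {
  pr <- make_profile(c(1, 2, 3, 4, 5, 6), zt = seq(0, 150, 30))
  lm <- detect_landmarks(pr, transition_zt = 150, window_start_zt = 0)
  expect_equal(lm$zt_min, 0)
  expect_equal(lm$zt_max, 120)  # last pre-transition bin

  over <- detect_landmarks(pr, 150, zt_min = 30, zt_max = 90)
  expect_true(over$manual)
  expect_equal(over$act_at_max, 4)

  flat <- make_profile(rep(3, 6), zt = seq(0, 150, 30))
  expect_error(detect_landmarks(flat, 150, 0), "no anticipation structure")
  # minimum in the final allowed bin: nothing can rise after it
  falling <- make_profile(c(6, 5, 4, 3, 2, 1), zt = seq(0, 150, 30))
  expect_error(detect_landmarks(falling, 150, 0), "no rise after the minimum")
  expect_error(detect_landmarks(pr, 150, 90), "at least 3 bins")
})

test_that("detected landmarks equal an exhaustive-scan oracle on simulations", {
  p <- lltc_protocol()
  for (s in 1:5) {
    prep <- daily_profile(simulate_population(
      sim_config(n_flies = 12, seed = 100 + s), p)$matrix, p, "TC6")
    lm <- detect_landmarks(prep$profile, 720)
    or <- oracle_landmarks(prep$profile$zt, prep$profile$median_value,
                           360, 720)
    expect_equal(lm$zt_min, or$zt_min)
    expect_equal(lm$zt_max, or$zt_max)
  }
})

test_that("the slope formula reproduces the printed worked example", {
  # median activity 0 at minute 511, 67.6 at minute 691
  s <- slope_between(0, 67.6, 511, 691)
  expect_equal(round(s, 2), 0.38)
  expect_equal(s, 67.6 / 180)
})

test_that("per-fly slopes carry sign and exclusions", {
  vals <- cbind(c(10, 10), c(30, 10), c(10, 30), c(NA, 50))
  n <- make_norm(vals, zt = c(510, 690))
  fs <- fly_slopes(n, 510, 690)
  expect_equal(unname(fs$slopes),
               c(0, (10 - 30) / 180, (30 - 10) / 180))
  expect_equal(fs$excluded, "fly_004")
  expect_error(fly_slopes(n, 500, 690), "existing bins")
})

test_that("slo_the composes the median profile with the slope formula", {
  set.seed(9)
  vals <- matrix(runif(10 * 7, 0, 100), 10, 7)
  n <- make_norm(vals)
  pr <- median_profile(n)
  expect_equal(slo_the(pr, 0, 270),
               slope_between(oracle_median(vals[1, ]),
                             oracle_median(vals[10, ]), 0, 270))
  # identical flies: slo_the equals every individual slope
  same <- make_norm(matrix(rep(c(0, 40, 80), 5), 3, 5))
  pr2 <- median_profile(same)
  expect_equal(slo_the(pr2, 0, 60),
               unname(fly_slopes(same, 0, 60)$slopes[1]))
})

test_that("slo_exp is the median of the individual slopes", {
  expect_equal(slo_exp(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(slo_exp(0.7), 0.7)
  set.seed(2)
  x <- rnorm(24)
  expect_equal(slo_exp(x), oracle_median(x))
})

test_that("the synchronization ratio guards its sign conventions", {
  expect_equal(sync_ratio(0.19, 0.38), 0.5)
  expect_error(sync_ratio(0.1, 0), "non-positive")
  expect_error(sync_ratio(0.1, -0.2), "non-positive")
  expect_equal(sync_ratio(-0.1, -0.2, direction = "downhill"), 0.5)
  expect_error(sync_ratio(-0.1, 0.2, direction = "downhill"), "downhill")
})

test_that("the half-threshold classifier follows the rule in both directions", {
  cls <- classify_anticipation(c(a = 0.1, b = 0.2, c = 0.3), 0.25)
  expect_equal(unname(cls$anticipating), c(FALSE, TRUE, TRUE))
  expect_equal(cls$fraction, 100 * 2 / 3)
  expect_equal(classify_anticipation(rep(0.3, 8), 0.3)$fraction, 100)
  expect_equal(classify_anticipation(c(-0.1, 0, -0.5), 0.3)$fraction, 0)
  down <- classify_anticipation(c(-0.3, -0.1), -0.4, direction = "downhill")
  expect_equal(unname(down$anticipating), c(TRUE, FALSE))
})

test_that("identical flies give ratio exactly 1 and 100% anticipating", {
  for (s in 1:3) {
    set.seed(s)
    series <- runif(48, 10, 90)
    series[14] <- 0    # clear trough inside the search window...
    series[22] <- 99   # ...followed by a clear peak before the transition
    n <- make_norm(matrix(rep(series, 9), 48, 9))
    an <- analyze_slopes(n, median_profile(n), transition_zt = 720)
    expect_identical(an$ratio, 1)
    expect_identical(an$fraction_anticipating, 100)
  }
})

test_that("downhill analysis mirrors the uphill rules", {
  dec <- seq(90, 10, length.out = 9)
  n <- make_norm(matrix(rep(dec, 6), 9, 6), zt = seq(0, 240, 30))
  an <- analyze_downhill(n, median_profile(n), window_zt = c(0, 270))
  expect_equal(an$landmarks$zt_max, 0)
  expect_equal(an$landmarks$zt_min, 240)
  expect_true(all(an$fly_slopes < 0))
  expect_identical(an$ratio, 1)
  expect_equal(an$fraction_anticipating, 100)

  flat <- make_norm(matrix(5, 9, 4), zt = seq(0, 240, 30))
  expect_error(analyze_downhill(flat, median_profile(flat), c(0, 270)),
               "no anticipation structure")
})

test_that("downhill landmark ties pick first maximum then last minimum", {
  pr <- make_profile(c(20, 80, 80, 40, 10, 10, 30), zt = seq(0, 180, 30))
  n <- make_norm(matrix(rep(pr$median_value, 4), 7, 4), zt = pr$zt)
  an <- analyze_downhill(n, pr, window_zt = c(0, 210))
  expect_equal(an$landmarks$zt_max, 30)   # first of the tied maxima
  expect_equal(an$landmarks$zt_min, 150)  # last of the subsequent minima
})

test_that("a simulated half-arrhythmic free-run day yields ~50% steep decliners", {
  p <- standard_protocol("DDTC", 2, 3, 6, 5, days_free = 2)
  fr <- sapply(1:5, function(s) {
    cfg <- sim_preset("control_DDTC", n_flies = 60, seed = 300 + s)
    cfg$p_flat <- 0.5
    sim <- simulate_population(cfg, p)
    prep <- daily_profile(sim$matrix, p, "DD2")
    analyze_downhill(prep$norm, prep$profile, c(0, 720))$fraction_anticipating
  })
  expect_true(abs(mean(fr) - 50) < 10)
})

test_that("all statistics match the plain-loop oracle to 1e-12", {
  p <- lltc_protocol()
  for (s in 1:6) {
    prep <- daily_profile(simulate_population(
      sim_config(n_flies = 10, seed = 500 + s, p_desync = 0.3), p)$matrix,
      p, "TC6")
    med_or <- oracle_median_profile(prep$norm$values)
    expect_equal(prep$profile$median_value, med_or, tolerance = 1e-12)
    an <- analyze_slopes(prep$norm, prep$profile, 720)
    or_lm <- oracle_landmarks(prep$norm$zt, med_or, 360, 720)
    expect_identical(an$landmarks[c("zt_min", "zt_max")], or_lm)
    or_sl <- oracle_fly_slopes(prep$norm$values, prep$norm$zt,
                               or_lm$zt_min, or_lm$zt_max)
    expect_equal(unname(an$fly_slopes), or_sl, tolerance = 1e-12)
    expect_equal(an$slo_exp, oracle_median(or_sl), tolerance = 1e-12)
    i <- which(prep$norm$zt == or_lm$zt_min)
    j <- which(prep$norm$zt == or_lm$zt_max)
    or_the <- (med_or[j] - med_or[i]) / (or_lm$zt_max - or_lm$zt_min)
    expect_equal(an$slo_the, or_the, tolerance = 1e-12)
    expect_equal(an$ratio, oracle_median(or_sl) / or_the, tolerance = 1e-12)
    expect_equal(an$fraction_anticipating,
                 100 * sum(or_sl > 0.5 * or_the) / length(or_sl),
                 tolerance = 1e-12)
  }
})
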