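test_that("preset registry ships the four study scenarios with valid fields", {
  reg <- scenario_presets()
  expect_setequal(names(reg),
                  c("sitting", "sitting_deep_breathing", "standing", "supine"))
  for (p in reg) {
    expect_s3_class(p, "scenario_preset")
    expect_gt(p$target_sdnn, 0)
    expect_lte(p$target_rmssd, 2 * p$target_sdnn)
    expect_equal(p$dropout_rate, 0.01)
    expect_equal(p$duration, 180)
  }
  expect_equal(reg$sitting_deep_breathing$respiration_rate, 10)
  expect_gt(reg$sitting_deep_breathing$rsa_amplitude, 0)
  expect_error(get_scenario("prone"), "unknown scenario")
})

test_that("preset invariants reject unattainable SDNN/RMSSD pairs", {
  expect_error(scenario_preset("x", 800, target_sdnn = 10, target_rmssd = 25),
               "stationary")
  # boundary rho = -1 is attainable
  expect_s3_class(scenario_preset("x", 800, 10, 20), "scenario_preset")
  expect_error(scenario_preset("x", 800, 10, 5, dropout_rate = 1), "dropout")
})

test_that("zero-variance preset yields a constant series", {
  p <- scenario_preset("flat", 1000, target_sdnn = 0, target_rmssd = 0,
                       rsa_amplitude = 0)
  ibi <- generate_ibi_series(p, 50, seed = 1)
  expect_equal(ibi$intervals, rep(1000, 50))
  expect_equal(sdnn(ibi), 0)
  expect_equal(rmssd(ibi), 0)
})

test_that("generated series hits the supine target mean within 1%", {
  ibi <- generate_ibi_series(get_scenario("supine"), 10000, seed = 11)
  expect_lt(abs(mean(ibi$intervals) - 851.51) / 851.51, 0.01)
})

test_that("SDNN and RMSSD targets are recovered within 5% at n = 20000", {
  p <- scenario_preset("ar", 900, target_sdnn = 50, target_rmssd = 30,
                       rsa_amplitude = 0)
  ibi <- generate_ibi_series(p, 20000, seed = 5)
  expect_lt(abs(sdnn(ibi) - 50) / 50, 0.05)
  expect_lt(abs(rmssd(ibi) - 30) / 30, 0.05)
})

test_that("sample RMSSD^2/(2 SDNN^2) converges to 1 - rho1", {
  for (targets in list(c(50, 30), c(40, 60), c(60, 85))) {
    p <- scenario_preset("ar", 900, targets[1], targets[2],
                         rsa_amplitude = 0)
    ibi <- generate_ibi_series(p, 20000, seed = 21)
    rho_implied <- 1 - targets[2]^2 / (2 * targets[1]^2)
    ratio <- rmssd(ibi)^2 / (2 * sdnn(ibi)^2)
    expect_equal(ratio, 1 - rho_implied, tolerance = 0.1)
  }
})

test_that("shifting all intervals moves the mean but not SDNN/RMSSD", {
  ibi <- generate_ibi_series(get_scenario("sitting"), 500, seed = 3)
  shifted <- ibi_series(ibi$intervals + 120)
  expect_equal(mean(shifted$intervals), mean(ibi$intervals) + 120)
  expect_equal(sdnn(shifted), sdnn(ibi))
  expect_equal(rmssd(shifted), rmssd(ibi))
})

test_that("rendering forces length, beat count, and spacing", {
  r <- clean_recording(n_beats = 10, interval_ms = 1000)
  expect_equal(length(r$signal$values), ceiling(10 * 40))  # 10 s at 40 Hz
  expect_length(r$truth_indices, 10)
  expect_equal(unique(diff(r$truth_indices)), 40L)
})

test_that("zero-amplitude template renders wander plus noise only", {
  ibi <- ibi_series(rep(1000, 5))
  flat <- render_ppg(ibi, template = beat_template(amplitude = 0))
  expect_equal(flat$signal$values, rep(0, length(flat$signal$values)))
  wob <- render_ppg(ibi, template = beat_template(amplitude = 0),
                    wander_amplitude = 2, wander_freq = 0.5)
  t_s <- signal_times(wob$signal)
  expect_equal(wob$signal$values, 2 * sin(2 * pi * 0.5 * t_s))
})

test_that("rendering is deterministic per seed", {
  ibi <- ibi_series(rep(800, 8))
  a <- render_ppg(ibi, noise_sd = 0.1, seed = 42)
  b <- render_ppg(ibi, noise_sd = 0.1, seed = 42)
  c <- render_ppg(ibi, noise_sd = 0.1, seed = 43)
  expect_identical(a$signal$values, b$signal$values)
  expect_false(identical(a$signal$values, c$signal$values))
})

test_that("templates wider than the shortest interval are rejected", {
  ibi <- ibi_series(c(800, 400, 900))
  expect_error(render_ppg(ibi, template = beat_template(width_ms = 450)),
               "merge")
})

test_that("dropout marks the expected slots", {
  sig <- sampled_signal(rnorm(200), 40)
  none <- apply_dropout(sig, 0, seed = 1)
  expect_false(any(none$missing_mask))
  expect_equal(data_loss(none), 0)

  some <- apply_dropout(sig, 0.2, seed = 1)
  expect_true(all(is.na(some$values[some$missing_mask])))
  expect_equal(data_loss(some), 100 * mean(some$missing_mask))
  expect_error(apply_dropout(sig, 0.6, seed = 1), "0.5")
})

test_that("dropout on 4 slots can only produce the 5 enumerable losses", {
  sig <- sampled_signal(rnorm(4), 40)
  losses <- vapply(1:200, function(s)
    data_loss(apply_dropout(sig, 0.25, seed = s)), numeric(1))
  expect_true(all(losses %in% c(0, 25, 50, 75, 100)))
  expect_true(length(unique(losses)) > 1)
})

test_that("burst dropout keeps the expected overall loss", {
  sig <- sampled_signal(rnorm(5000), 40)
  losses <- vapply(1:50, function(s)
    data_loss(apply_dropout(sig, 0.05, seed = s, burst_mean = 4)),
    numeric(1))
  expect_equal(mean(losses), 5, tolerance = 0.15)
})

test_that("simulate_recording is bitwise deterministic and covers duration", {
  a <- simulate_recording("sitting", duration = 60, seed = 9)
  b <- simulate_recording("sitting", duration = 60, seed = 9)
  expect_identical(a$signal$values, b$signal$values)
  expect_identical(a$truth_ibi$intervals, b$truth_ibi$intervals)
  expect_identical(a$truth_indices, b$truth_indices)
  expect_lte(sum(a$truth_ibi$intervals), 60 * 1000)
  expect_gt(sum(a$truth_ibi$intervals), 55 * 1000)
  expect_length(a$truth_indices, length(a$truth_ibi))
})
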