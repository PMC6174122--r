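# Synthetic-data generator contracts: structure, determinism, round trips.

test_that("power profile sprint means follow the geometric decrement exactly", {
  rst <- generate_power_profile(5, peak_power = 600, decrement_rate = 0.1,
                                noise_sd = 0)
  expect_equal(rst$truth$sprint_mean_w, 600 * 0.9^(0:4))
  psp <- per_sprint_power(rst$power, rst$timeline)
  expect_equal(psp$mean_w, rst$truth$sprint_mean_w, tolerance = 1e-12)
})

test_that("single no-decay sprint gives one plateau and recovery at 20 W", {
  rst <- generate_power_profile(1, peak_power = 800, decrement_rate = 0,
                                noise_sd = 0)
  expect_equal(n_sprints(rst$timeline), 1)
  psp <- per_sprint_power(rst$power, rst$timeline)
  expect_equal(psp$mean_w, 800)
  # recovery segment sits at the ergometer's 20 W resistance
  rec <- bfrsprint:::interval_index(rst$power, rst$timeline$end[1] + 1,
                        rst$timeline$recovery_end[1])
  expect_true(all(rst$power$values[rec] == 20))
})

test_that("timelines alternate sprint and recovery at configured durations", {
  rst <- generate_power_profile(8, 650, 0.02, 0)
  tl <- rst$timeline
  expect_equal(tl$end - tl$start, rep(10, 8))
  expect_equal(tl$recovery_end - tl$end, rep(20, 8))
  expect_equal(tl$start[-1], tl$recovery_end[-8])
  # traces cover the full protocol span
  expect_gte(length(rst$power$values) / rst$power$fs, max(tl$recovery_end))
})

test_that("generator input validation", {
  expect_error(generate_power_profile(0, 600), ">= 1")
  expect_error(generate_power_profile(5, -10), "positive")
  expect_error(generate_power_profile(5, 600, decrement_rate = 1), "\\[0, 1\\)")
  rst <- generate_power_profile(3, 600, 0.1, 0)
  expect_error(generate_nirs_traces(rst$timeline, delta_schedule = c(1, 2)),
               "length")
  expect_error(generate_neuromuscular_traces(val_true = 120), "\\[0, 100\\]")
})

test_that("identical seeds give bit-identical datasets", {
  a <- generate_power_profile(5, 600, 0.05, noise_sd = 20, seed = 42)
  b <- generate_power_profile(5, 600, 0.05, noise_sd = 20, seed = 42)
  expect_identical(a$power$values, b$power$values)
  na <- generate_nirs_traces(a$timeline, delta_schedule = rep(8, 5),
                             artifact_amp = 3, noise_sd = 0.2, seed = 7)
  nb <- generate_nirs_traces(b$timeline, delta_schedule = rep(8, 5),
                             artifact_amp = 3, noise_sd = 0.2, seed = 7)
  expect_identical(na$hhb$values, nb$hhb$values)
  sa <- generate_study(n_participants = 2, seed = 3, signals = FALSE)
  sb <- generate_study(n_participants = 2, seed = 3, signals = FALSE)
  expect_identical(sa$truth, sb$truth)
})

test_that("HHb rises within each sprint (max after min) by construction", {
  fix <- make_clean_rst(n_sprints = 4, deltas = c(9, 8, 7, 6))
  for (k in 1:4) {
    idx <- bfrsprint:::interval_index(fix$nirs$hhb, fix$timeline$start[k],
                          fix$timeline$end[k])
    v <- bfrsprint:::clean_values(fix$nirs$hhb)[idx]
    expect_gt(which.max(v), which.min(v))
  }
})

test_that("single-sprint NIRS round trip recovers the delta exactly", {
  rst <- generate_power_profile(1, 600, 0, 0)
  nir <- generate_nirs_traces(rst$timeline, delta_schedule = 10)
  expect_equal(sprint_deltas(nir$hhb, rst$timeline), 10)
})

test_that("neuromuscular generator round-trips every metric at <= 0.1%", {
  nm <- generate_neuromuscular_traces(mvc_true = 300, val_true = 85,
                                      p100 = 60, p10 = 54, twitch = 30,
                                      emg_rms = 0.15, m_wave_pp = 2.5,
                                      noise_sd = 0, emg_noise_sd = 0)
  a <- analyze_neuromuscular(nm$force, nm$emg, nm$markers, phase = "pre")
  expect_equal(a$mvc_n, 300, tolerance = 1e-3)
  expect_equal(a$val_pct, 85, tolerance = 1e-3)
  expect_equal(a$p100_n, 60, tolerance = 1e-3)
  expect_equal(a$p10_n, 54, tolerance = 1e-3)
  expect_equal(a$twitch_n, 30, tolerance = 1e-3)
  expect_equal(a$p10_over_p100, 0.9, tolerance = 1e-3)
  expect_equal(a$emg_rms_mv, 0.15, tolerance = 1e-3)
  expect_equal(a$m_wave_pp_mv, 2.5, tolerance = 1e-3)
  expect_equal(a$rms_over_mwave, 0.06, tolerance = 1e-3)
})

test_that("full activation yields a zero superimposed increment", {
  nm <- generate_neuromuscular_traces(val_true = 100, noise_sd = 0)
  expect_equal(nm$truth$superimposed, 0)
  a <- analyze_neuromuscular(nm$force, nm$emg, nm$markers)
  expect_equal(a$val_pct, 100, tolerance = 1e-6)
})

test_that("markers are ordered with at least 2-s spacing", {
  nm <- generate_neuromuscular_traces()
  expect_true(all(diff(nm$markers$time_s) >= 2))
})

test_that("study structure covers participants x conditions with truth", {
  st <- generate_study(n_participants = 3, seed = 5, signals = FALSE)
  expect_equal(nrow(st$truth), 9)
  expect_setequal(unique(st$truth$condition), c(0, 45, 60))
  expect_true(all(st$truth$n_sprints >= 2))
  expect_true(all(st$truth$val_pre >= 0 & st$truth$val_pre <= 100))
  expect_error(generate_study(n_participants = 1), ">= 2")
})

test_that("simulate_endpoints applies per-subject multiplicative effects", {
  d <- simulate_endpoints(200, baseline = 30, participant_sd = 10,
                          residual_sd = 0.01,
                          mult = c(`0` = 1, `45` = 0.5), seed = 8)
  wide <- merge(d[d$condition == "0", ], d[d$condition == "45", ],
                by = "participant")
  expect_equal(mean(wide$value.y / wide$value.x), 0.5, tolerance = 0.01)
})
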