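# Sprint performance and metabolic endpoints.

test_that("fatigue index hand-computed cases", {
  expect_equal(fatigue_index(c(600, 600, 600)), 0)
  expect_equal(fatigue_index(c(600, 540, 486, 437.4)),
               (1 - mean(c(600, 540, 486, 437.4)) / 600) * 100)
  expect_equal(fatigue_index(c(600, 540, 486, 437.4)), 14.025)
  # best of the FIRST TWO sprints, even when a later sprint is lower
  expect_equal(fatigue_index(c(500, 600, 300)),
               (1 - mean(c(500, 600, 300)) / 600) * 100)
  expect_error(fatigue_index(600), "fewer than 2")
  expect_error(fatigue_index(c(0, 0, 0)), "positive")
})

test_that("fatigue index is scale-invariant and zero iff constant at best", {
  p <- c(620, 600, 550, 480)
  for (c in c(0.5, 2, 10))
    expect_equal(fatigue_index(c * p), fatigue_index(p))
  expect_equal(fatigue_index(rep(444, 6)), 0)
  expect_gt(fatigue_index(c(600, 600, 599)), 0)
})

test_that("fatigue index matches the geometric closed form on generator data", {
  n <- 30; r <- 1 - 0.02
  rst <- generate_power_profile(n, 700, decrement_rate = 0.02, noise_sd = 0)
  psp <- per_sprint_power(rst$power, rst$timeline)
  closed <- (1 - mean(r^(0:(n - 1)))) * 100
  expect_equal(fatigue_index(psp$mean_w), closed, tolerance = 1e-10)
})

test_that("per-sprint power: constant and trapezoid cases", {
  tl <- sprint_timeline(0, 10)
  const <- channel_trace(rep(600, 120), 10)
  psp <- per_sprint_power(const, tl)
  expect_equal(psp$mean_w, 600)
  expect_equal(psp$peak_w, 600)
  # trapezoid 0 -> 600 W over 0.5 s then plateau: continuous mean 585 W
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  trap <- channel_trace(600 * pmin(1, t / 0.5), 1000)
  expect_equal(per_sprint_power(trap, tl)$mean_w, 585, tolerance = 0.5)
  expect_error(per_sprint_power(const, sprint_timeline(numeric(0), numeric(0))),
               "no sprints")
})

test_that("total work: closed-form cases and additivity over sprints", {
  tl1 <- sprint_timeline(0, 10)
  p1 <- channel_trace(rep(600, 150), 10)
  expect_equal(total_work(p1, tl1), 6)
  tl2 <- sprint_timeline(c(0, 30), c(10, 40))
  v <- rep(20, 500); v[1:100] <- 600; v[301:400] <- 500
  p2 <- channel_trace(v, 10)
  expect_equal(total_work(p2, tl2), 11)
  # additivity: sum of single-sprint timelines equals the full timeline
  w1 <- total_work(p2, sprint_timeline(0, 10))
  w2 <- total_work(p2, sprint_timeline(30, 40))
  expect_equal(w1 + w2, total_work(p2, tl2))
})

test_that("pacing validation applies the 95% warm-up rule", {
  expect_true(validate_pacing(c(750, 740), 780))   # 750 >= 741
  expect_false(validate_pacing(c(700, 690), 780))  # 700 < 741
  expect_true(validate_pacing(c(780, 600), 780))   # 100% >= 95%
})

test_that("task failure requires a sustained cadence drop", {
  tl <- sprint_timeline(c(0, 30, 60), c(10, 40, 70))
  fs <- 10
  cad <- rep(90, 800)
  none <- channel_trace(cad, fs)
  expect_true(is.na(detect_task_failure(none, tl)))
  # 2-s dip below threshold in sprint 2 -> failure at sprint 2
  cad2 <- cad; cad2[330:350] <- 60
  expect_equal(detect_task_failure(channel_trace(cad2, fs), tl), 2)
  # 0.3-s dip only: below the 1-s dwell, ignored
  cad3 <- cad; cad3[330:332] <- 60
  expect_true(is.na(detect_task_failure(channel_trace(cad3, fs), tl)))
})

test_that("vo2 peak: constant, step, and spike cases", {
  t <- 0:120
  expect_equal(vo2_peak(t, rep(2.5, 121)), 2.5)
  step <- ifelse(t < 60, 2, 3)
  expect_equal(vo2_peak(t, step), 3)
  spike <- rep(2, 121); spike[61] <- 3.5
  expect_lt(vo2_peak(t, spike), 3.5)
  expect_error(vo2_peak(0:20, rep(2, 21)), "shorter than")
})

test_that("vo2 peak equals the brute-force window maximum on irregular series", {
  set.seed(31)
  for (r in 1:12) {
    tt <- cumsum(runif(80, 0.4, 1.6))
    vv <- 2 + cumsum(rnorm(80, 0, 0.05))
    expect_equal(vo2_peak(tt, vv), vo2_peak_bruteforce(tt, vv),
                 tolerance = 1e-10)
  }
})

test_that("spo2 summary takes the lowest stable run of the final minute", {
  # 0.2 Hz: the last 12 samples cover the final minute; a leading block at
  # 99% sits outside it and must not contribute
  v <- c(rep(99, 12), rep(95, 6), 95, 94, 94, 94, 85, 93)
  tr <- channel_trace(v, 0.2)
  expect_equal(spo2_summary(tr), 94)          # isolated 85 is not stable
  expect_equal(spo2_summary(channel_trace(rep(94, 24), 0.2)), 94)
  jagged <- channel_trace(c(rep(99, 12), rep(c(98, 88, 97, 85, 96, 84), 2)),
                          0.2)
  expect_warning(out <- spo2_summary(jagged), "no stable run")
  expect_equal(out, 84)
})

test_that("summarize_sprint_test assembles the per-test endpoint row", {
  rst <- generate_power_profile(6, 650, 0.03, 0)
  row <- summarize_sprint_test(rst$power, rst$timeline, cadence = rst$cadence,
                               scalars = list(lactate = 8.1))
  expect_equal(row$n_sprints, 6)
  expect_equal(row$mean_power_w, mean(rst$truth$sprint_mean_w))
  expect_equal(row$failure_sprint, 6)  # generator dips cadence in the last sprint
  expect_equal(row$lactate, 8.1)
})
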