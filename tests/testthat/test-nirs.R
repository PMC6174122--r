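# NIRS processing: total hemoglobin, segmentation, per-sprint deltas,
# set-duration normalisation.

test_that("total hemoglobin is the pointwise chromophore sum", {
  o2 <- channel_trace(c(-3, 0, 2), 10, channel = "O2Hb", site = "vastus_lateralis")
  hh <- channel_trace(c(5, 0, -1), 10, channel = "HHb", site = "vastus_lateralis")
  th <- total_hemoglobin(o2, hh)
  expect_equal(th$values, c(2, 0, 1))
  # identity when HHb is zero
  z <- channel_trace(rep(0, 3), 10, site = "vastus_lateralis")
  expect_equal(total_hemoglobin(o2, z)$values, o2$values)
  # mismatched channels rejected
  expect_error(total_hemoglobin(o2, channel_trace(1:5, 10)), "must match")
})

test_that("per-sprint deltas: endpoint extremes, constants, and guards", {
  tl <- sprint_timeline(0, 1)
  rising <- channel_trace(seq(2, 9, length.out = 10), 10)
  expect_equal(sprint_deltas(rising, tl), 7)
  flat <- channel_trace(rep(4, 10), 10)
  expect_equal(sprint_deltas(flat, tl), 0)
  expect_error(sprint_deltas(rising, sprint_timeline(numeric(0), numeric(0))),
               "no sprints")
})

test_that("deltas are translation-invariant and scale linearly", {
  fix <- make_clean_rst()
  hhf <- lowpass_zero_phase(fix$nirs$hhb)
  d0 <- sprint_deltas(hhf, fix$timeline)
  shifted <- hhf; shifted$values <- shifted$values + 13.7
  expect_equal(sprint_deltas(shifted, fix$timeline), d0)
  for (c in c(2.5, -3)) {
    scaled <- hhf; scaled$values <- scaled$values * c
    expect_equal(sprint_deltas(scaled, fix$timeline), abs(c) * d0)
  }
})

test_that("noise-free filtered deltas match the generator schedule", {
  fix <- make_clean_rst(deltas = c(10, 9, 8, 7, 6))
  hhf <- lowpass_zero_phase(fix$nirs$hhb)
  o2f <- lowpass_zero_phase(fix$nirs$o2hb)
  expect_equal(sprint_deltas(hhf, fix$timeline), c(10, 9, 8, 7, 6),
               tolerance = 0.01)
  expect_equal(sprint_deltas(o2f, fix$timeline), fix$nirs$truth$delta_o2hb,
               tolerance = 0.01)
})

test_that("segmentation honours an ergometer timeline hint exactly", {
  fix <- make_clean_rst()
  hhf <- lowpass_zero_phase(fix$nirs$hhb)
  expect_identical(segment_sprints(hhf, timeline_hint = fix$timeline),
                   fix$timeline)
})

test_that("flat signals yield an empty timeline with a warning", {
  tr <- channel_trace(rep(0, 3000), 10)
  expect_warning(tl <- segment_sprints(tr), "no sprint/recovery alternation")
  expect_equal(n_sprints(tl), 0)
})

test_that("automatic segmentation recovers count and onsets on clean data", {
  fix <- make_clean_rst(n_sprints = 10, deltas = rep(8, 10))
  hhf <- lowpass_zero_phase(fix$nirs$hhb)
  tl <- segment_sprints(hhf)
  expect_equal(n_sprints(tl), 10)
  expect_lt(max(abs(tl$start - fix$timeline$start)), 0.5)
})

test_that("set-duration normalisation is exact at integer alignment", {
  v5 <- c(10, 9, 8, 7, 6)
  expect_equal(unname(normalize_set_duration(v5)), v5)
  v10 <- seq(20, 11)
  expect_equal(unname(normalize_set_duration(v10)), v10[c(2, 4, 6, 8, 10)])
})

test_that("set-duration normalisation interpolates fractional indices", {
  v7 <- c(10, 9, 8, 7, 6, 5, 4)
  got <- normalize_set_duration(v7)
  # f = 0.2 -> p = 1.4 -> 0.6 v1 + 0.4 v2
  expect_equal(unname(got[1]), 0.6 * 10 + 0.4 * 9)
  # independent piecewise-linear evaluator
  oracle <- approx(seq_along(v7), v7, xout = pmax(1, c(0.2, 0.4, 0.6, 0.8, 1) * 7))$y
  expect_equal(unname(got), oracle)
  # final fraction always the last sprint exactly
  expect_equal(unname(got[5]), 4)
  expect_error(normalize_set_duration(numeric(0)), "at least one")
})

test_that("nirs_sprint_summary reports all channels per sprint", {
  fix <- make_clean_rst()
  s <- nirs_sprint_summary(fix$nirs$o2hb, fix$nirs$hhb, fix$nirs$tsi,
                           timeline = fix$timeline)
  expect_equal(nrow(s), 5)
  expect_equal(s$delta_hhb, c(10, 9, 8, 7, 6), tolerance = 0.01)
  expect_equal(s$delta_thb, fix$nirs$truth$delta_thb, tolerance = 0.02)
  expect_equal(s$tsi_max, fix$nirs$truth$tsi_max, tolerance = 0.05)
})
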