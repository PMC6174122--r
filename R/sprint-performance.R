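# Sprint performance and metabolic endpoint summaries: per-sprint power,
# fatigue index, total work, pacing validity, task failure, 30-s peak oxygen
# uptake, and pulse-oximetry summaries.

#' Per-sprint mean and peak power
#'
#' Time-averages the crank power trace over each sprint interval and records
#' the per-sprint maximum sample.
#'
#' @param power A power [channel_trace()] (W).
#' @param timeline A [sprint_timeline()] within the trace span.
#' @return Data frame with columns `sprint`, `mean_w`, `peak_w`.
#' @export
per_sprint_power <- function(power, timeline) {
  stopifnot(inherits(power, "channel_trace"),
            inherits(timeline, "sprint_timeline"))
  if (n_sprints(timeline) < 1L) stop("timeline has no sprints")
  res <- lapply(seq_len(n_sprints(timeline)), function(k) {
    idx <- interval_index(power, timeline$start[k], timeline$end[k])
    if (length(idx) == 0L)
      stop(sprintf("sprint %d maps to an empty sample window", k))
    v <- power$values[idx]
    c(mean(v), max(v))
  })
  m <- do.call(rbind, res)
  data.frame(sprint = seq_len(n_sprints(timeline)),
             mean_w = m[, 1], peak_w = m[, 2])
}

#' Fatigue index (percent decrement) of a repeated-sprint test
#'
#' `S_dec = (1 - S_bar / S_best) * 100`, where `S_bar` is the mean of all
#' per-sprint mean powers and `S_best` is the higher mean power of the first
#' two sprints. Constant powers give 0; the index is invariant to scaling
#' all powers by a positive constant.
#'
#' @param per_sprint_mean_powers Numeric vector of per-sprint mean powers
#'   (W), at least two sprints.
#' @return The percent decrement (single number).
#' @export
#' @examples
#' fatigue_index(c(600, 540, 486, 437.4))  # 14.025
fatigue_index <- function(per_sprint_mean_powers) {
  p <- as.numeric(per_sprint_mean_powers)
  if (length(p) < 2L)
    stop("fatigue index is undefined for fewer than 2 sprints")
  s_best <- max(p[1:2])
  if (s_best <= 0) stop("best sprint power must be positive")
  (1 - mean(p) / s_best) * 100
}

#' Total work of a repeated-sprint test
#'
#' Sum over sprints of the time integral of power, reported in kJ. With the
#' package's half-open sprint windows the rectangle Riemann sum is the exact
#' discrete integral: a constant P over a D-second sprint gives P * D.
#'
#' @inheritParams per_sprint_power
#' @return Total work in kJ.
#' @export
total_work <- function(power, timeline) {
  stopifnot(inherits(power, "channel_trace"),
            inherits(timeline, "sprint_timeline"))
  if (n_sprints(timeline) < 1L) stop("timeline has no sprints")
  dt <- 1 / power$fs
  w <- vapply(seq_len(n_sprints(timeline)), function(k) {
    idx <- interval_index(power, timeline$start[k], timeline$end[k])
    sum(power$values[idx]) * dt
  }, numeric(1))
  sum(w) / 1000
}

#' Validate the anti-pacing rule of the first two sprints
#'
#' The first two sprints must reach at least `threshold` (default 95 %) of
#' the peak power of the best warm-up sprint, guarding against pacing.
#'
#' @param first_two_sprint_peaks Numeric vector (length 2) of the first two
#'   sprints' peak powers (W).
#' @param warmup_best_peak Peak power of the best warm-up sprint (W).
#' @param threshold Fraction of the warm-up peak required, default 0.95.
#' @return `TRUE` if the pacing criterion is met.
#' @export
validate_pacing <- function(first_two_sprint_peaks, warmup_best_peak,
                            threshold = 0.95) {
  if (length(first_two_sprint_peaks) < 1L || warmup_best_peak <= 0)
    stop("need sprint peaks and a positive warm-up peak")
  max(first_two_sprint_peaks[seq_len(min(2L, length(first_two_sprint_peaks)))]) >=
    threshold * warmup_best_peak
}

#' Detect task failure from the cadence trace
#'
#' Task failure terminates the test when cadence drops below
#' `threshold_rpm` (default 70) for at least `dwell_s` seconds within a
#' sprint; single-sample dropouts shorter than the dwell are ignored.
#'
#' @param cadence A cadence [channel_trace()] (rpm).
#' @param timeline A [sprint_timeline()].
#' @param threshold_rpm Failure threshold, default 70 rpm.
#' @param dwell_s Minimum below-threshold duration (s), default 1.
#' @return The index of the failing sprint, or `NA_integer_` if none.
#' @export
detect_task_failure <- function(cadence, timeline, threshold_rpm = 70,
                                dwell_s = 1) {
  stopifnot(inherits(cadence, "channel_trace"),
            inherits(timeline, "sprint_timeline"))
  need <- ceiling(dwell_s * cadence$fs)
  for (k in seq_len(n_sprints(timeline))) {
    idx <- interval_index(cadence, timeline$start[k], timeline$end[k])
    below <- cadence$values[idx] < threshold_rpm
    r <- rle(below)
    if (any(r$values & r$lengths >= need)) return(k)
  }
  NA_integer_
}

#' Peak oxygen uptake as the highest 30-s average
#'
#' Treats the breath-by-breath record as a step function (each breath's
#' value holds until the next breath) and returns the maximum time-weighted
#' average over all 30-s windows anchored at breath times.
#'
#' @param time_s Breath timestamps (s), strictly increasing.
#' @param vo2 Oxygen uptake per breath (L/min).
#' @param window_s Averaging window (s), default 30.
#' @return The peak windowed average (L/min).
#' @export
vo2_peak <- function(time_s, vo2, window_s = 30) {
  time_s <- as.numeric(time_s); vo2 <- as.numeric(vo2)
  if (length(time_s) != length(vo2) || length(time_s) < 2L)
    stop("need matching breath times and values (>= 2 breaths)")
  if (any(diff(time_s) <= 0)) stop("breath times must be strictly increasing")
  span <- time_s[length(time_s)] - time_s[1L]
  if (span < window_s)
    stop(sprintf("record (%.1f s) shorter than the %g-s averaging window",
                 span, window_s))
  # cumulative integral of the step function at breath times
  n <- length(time_s)
  seg <- vo2[-n] * diff(time_s)
  cum <- c(0, cumsum(seg))  # integral from time_s[1] to time_s[i]
  int_at <- function(tt) {
    # integral of the step function from time_s[1] to tt
    i <- findInterval(tt, time_s)
    cum[i] + vo2[pmin(i, n - 1L)] * (tt - time_s[i]) * (i < n)
  }
  anchors <- time_s[time_s + window_s <= time_s[n] + 1e-9]
  vals <- (int_at(anchors + window_s) - int_at(anchors)) / window_s
  max(vals)
}

#' Lowest stable pulse-oximetry value of the final minute
#'
#' Operationalises "lowest stable value": within the final minute, every run
#' of at least `min_run` consecutive samples whose range does not exceed
#' `max_range` percentage points is a stable run; the minimum run mean is
#' returned. If no stable run exists the plain minimum is returned with a
#' warning.
#'
#' @param spo2 An SpO2 [channel_trace()] (%).
#' @param final_minute Numeric length-2 interval (s) defining the final
#'   minute; default the last 60 s of the trace.
#' @param min_run Minimum run length in samples, default 3.
#' @param max_range Maximum within-run range (percentage points), default 2.
#' @return The summary SpO2 value (%).
#' @export
spo2_summary <- function(spo2, final_minute = NULL, min_run = 3L,
                         max_range = 2) {
  stopifnot(inherits(spo2, "channel_trace"))
  t_end <- (length(spo2$values) - 1) / spo2$fs
  if (is.null(final_minute)) final_minute <- c(max(0, t_end - 60), t_end)
  idx <- interval_index(spo2, final_minute[1], final_minute[2] + 1e-9)
  v <- spo2$values[idx]
  if (length(v) < min_run) {
    warning("final-minute window too short for a stable run; using minimum")
    return(min(v))
  }
  means <- numeric(0)
  for (s in seq_len(length(v) - min_run + 1L)) {
    w <- v[s:(s + min_run - 1L)]
    if (max(w) - min(w) <= max_range) means <- c(means, mean(w))
  }
  if (length(means) == 0L) {
    warning("no stable run in the final minute; using minimum")
    return(min(v))
  }
  min(means)
}

#' Summarise one repeated-sprint test
#'
#' Produces the per-test endpoint row: sprint count, mean power, fatigue
#' index, total work, maximal heart rate, SpO2 summary, 30-s peak oxygen
#' uptake, and pass-through scalars.
#'
#' @param power,cadence [channel_trace()] objects.
#' @param timeline A [sprint_timeline()].
#' @param vo2 Data frame with `time_s`, `value` (breath-by-breath), or
#'   `NULL`.
#' @param hr,spo2 Optional [channel_trace()] objects.
#' @param scalars Optional named list of scalar endpoints (lactate, RPE ...)
#'   copied into the row.
#' @return One-row data frame.
#' @export
summarize_sprint_test <- function(power, timeline, cadence = NULL,
                                  vo2 = NULL, hr = NULL, spo2 = NULL,
                                  scalars = NULL) {
  psp <- per_sprint_power(power, timeline)
  out <- data.frame(
    n_sprints = n_sprints(timeline),
    mean_power_w = mean(psp$mean_w),
    fatigue_index_pct = if (nrow(psp) >= 2) fatigue_index(psp$mean_w) else NA_real_,
    total_work_kj = total_work(power, timeline),
    failure_sprint = if (!is.null(cadence))
      detect_task_failure(cadence, timeline) else NA_integer_,
    hr_max = if (!is.null(hr)) max(hr$values) else NA_real_,
    spo2_pct = if (!is.null(spo2)) spo2_summary(spo2) else NA_real_,
    vo2_lmin = if (!is.null(vo2)) vo2_peak(vo2$time_s, vo2$value) else NA_real_
  )
  if (!is.null(scalars)) for (nm in names(scalars)) out[[nm]] <- scalars[[nm]]
  out
}
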