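# Synthetic repeated-sprint test generator: crank power, cadence and the
# protocol timeline with known per-sprint ground truth.

#' Generate a synthetic repeated-sprint power and cadence profile
#'
#' Builds the ergometer channels of one repeated-sprint test to exhaustion:
#' `n_sprints` sprints of `sprint_duration_s` seconds separated by active
#' recovery at a fixed ergometer resistance, preceded by a lead-in and
#' followed by a tail at the same resistance. Each sprint is a trapezoid: a
#' 0.5-s rise to a plateau. The plateau is scaled so the sampled mean power
#' of sprint `k` equals `peak_power * (1 - decrement_rate)^(k-1)` exactly,
#' making the fatigue index of the noise-free profile available in closed
#' form. Cadence is high during sprints and drops with power; when
#' `fail_last = TRUE` the final sprint ends with cadence below the task
#' failure threshold, emulating test termination.
#'
#' @param n_sprints Number of sprints (>= 1).
#' @param peak_power Mean power of the first sprint (W, > 0).
#' @param decrement_rate Per-sprint geometric decrement in `[0, 1)`.
#' @param noise_sd SD of additive Gaussian noise on the power trace (W).
#' @param seed Optional integer seed (local to this call).
#' @param fs Sampling rate (Hz), default 10.
#' @param sprint_duration_s,recovery_duration_s Protocol durations (s).
#' @param lead_in_s,tail_s Pre-test and post-test recovery-resistance spans (s).
#' @param recovery_power Ergometer resistance between sprints (W), default 20.
#' @param rise_time_s Trapezoid rise time (s), default 0.5.
#' @param fail_last Dip cadence below 70 rpm for the last 2 s of the final
#'   sprint (default `TRUE`).
#' @return A list with elements `power` and `cadence` ([channel_trace()]),
#'   `timeline` ([sprint_timeline()]), and `truth` (list with the noise-free
#'   per-sprint mean and peak powers).
#' @export
#' @examples
#' rst <- generate_power_profile(5, peak_power = 600, decrement_rate = 0.1)
#' rst$truth$sprint_mean_w  # 600, 540, 486, ...
generate_power_profile <- function(n_sprints, peak_power = 700,
                                   decrement_rate = 0.02, noise_sd = 0,
                                   seed = NULL, fs = 10,
                                   sprint_duration_s = 10,
                                   recovery_duration_s = 20,
                                   lead_in_s = 30, tail_s = 30,
                                   recovery_power = 20, rise_time_s = 0.5,
                                   fail_last = TRUE) {
  if (n_sprints < 1L) stop("`n_sprints` must be >= 1")
  if (peak_power <= 0) stop("`peak_power` must be positive")
  if (decrement_rate < 0 || decrement_rate >= 1)
    stop("`decrement_rate` must be in [0, 1)")
  if (sprint_duration_s <= 0 || recovery_duration_s <= 0)
    stop("durations must be positive")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  dt <- 1 / fs
  starts <- lead_in_s + (seq_len(n_sprints) - 1) *
    (sprint_duration_s + recovery_duration_s)
  ends <- starts + sprint_duration_s
  timeline <- sprint_timeline(starts, ends,
                              recovery_end = ends + recovery_duration_s)
  total_s <- ends[n_sprints] + tail_s
  t <- seq(0, total_s - dt, by = dt)
  power <- rep(recovery_power, length(t))
  cadence <- rep(85, length(t))

  target_mean <- peak_power * (1 - decrement_rate)^(seq_len(n_sprints) - 1)
  truth_peak <- numeric(n_sprints)
  for (k in seq_len(n_sprints)) {
    idx <- which(t >= starts[k] - 1e-9 & t < ends[k] - 1e-9)
    shape <- pmin(1, (t[idx] - starts[k]) / rise_time_s)
    plateau <- target_mean[k] / mean(shape)
    power[idx] <- plateau * shape
    truth_peak[k] <- plateau
    cad_k <- 85 + 35 * min(1, target_mean[k] / peak_power)
    cadence[idx] <- cad_k
    if (fail_last && k == n_sprints) {
      dip <- which(t[idx] >= ends[k] - 2)
      cadence[idx][dip] <- 60
    }
  }
  if (noise_sd > 0) power <- power + rnorm(length(power), 0, noise_sd)
  pw <- channel_trace(power, fs, channel = "power", units = "W")
  cd <- channel_trace(cadence, fs, channel = "cadence", units = "rpm")
  list(power = pw, cadence = cd, timeline = timeline,
       truth = list(sprint_mean_w = target_mean, sprint_peak_w = truth_peak))
}

#' Generate synthetic NIRS traces for one repeated-sprint test
#'
#' Produces oxy-/deoxyhemoglobin concentration changes and tissue saturation
#' index for one site, locked to a sprint timeline. Within each sprint
#' \[HHb\] rises along a smooth raised-cosine saturation (zero slope at the
#' sprint boundaries) and \[O2Hb\] falls with mirrored kinetics; each
#' recovery relaxes a fraction `recover_frac` of the preceding rise back
#' toward baseline, again with zero boundary slope, so the whole noise-free
#' signal is continuously differentiable and its energy sits well below the
#' 0.2 Hz analysis cutoff. Amplitudes are scaled so the per-sprint
#' max-minus-min of the noise-free component equals the requested delta
#' schedule exactly under the package's half-open sampling convention. A
#' sinusoidal pedal-stroke artifact, linear drift and Gaussian noise are
#' superimposed; the noise-free component of every channel is stored in the
#' `"clean"` attribute so recovery tests never re-derive ground truth from
#' noisy data. Total hemoglobin is not generated: it is derived downstream
#' as the sum of the two chromophores.
#'
#' @param timeline A [sprint_timeline()].
#' @param site `"vastus_lateralis"` or `"prefrontal_cortex"` (metadata).
#' @param delta_schedule Per-sprint target max-min of \[HHb\] (uM).
#' @param o2hb_schedule Per-sprint target max-min of \[O2Hb\] (uM); defaults
#'   to `delta_schedule` minus `thb_schedule` so the derived \[tHb\] delta is
#'   controllable.
#' @param thb_schedule Per-sprint target \[tHb\] delta (uM) used only to set
#'   the default `o2hb_schedule`; default 2.
#' @param tsi_baseline Resting TSI (%), default 68.
#' @param tsi_drop_schedule Per-sprint TSI desaturation depth (%); default
#'   scales with `delta_schedule`.
#' @param artifact_freq Pedal-stroke artifact frequency (Hz); must exceed the
#'   0.2 Hz analysis cutoff. Default 1.4.
#' @param artifact_amp Artifact amplitude (uM), default 0.
#' @param drift Linear drift (uM/min), default 0.
#' @param noise_sd Gaussian noise SD (uM), default 0.
#' @param seed Optional integer seed (local to this call).
#' @param fs Sampling rate (Hz), default 10.
#' @param recover_frac Fraction of each sprint's rise relaxed back during
#'   the following recovery (default 0.9, leaving a small progressive
#'   baseline drift across the set).
#' @param tail_s Trace continuation after the last recovery (s).
#' @return List of `channel_trace` objects `o2hb`, `hhb`, `tsi`, each with a
#'   `"clean"` attribute, plus `truth` (the realised clean per-sprint deltas
#'   and TSI maxima).
#' @export
generate_nirs_traces <- function(timeline,
                                 site = c("vastus_lateralis",
                                          "prefrontal_cortex"),
                                 delta_schedule,
                                 o2hb_schedule = NULL,
                                 thb_schedule = 2,
                                 tsi_baseline = 68,
                                 tsi_drop_schedule = NULL,
                                 artifact_freq = 1.4, artifact_amp = 0,
                                 drift = 0, noise_sd = 0, seed = NULL,
                                 fs = 10, recover_frac = 0.9,
                                 tail_s = 20) {
  site <- match.arg(site)
  stopifnot(inherits(timeline, "sprint_timeline"))
  n <- n_sprints(timeline)
  if (n < 1L) stop("timeline must contain at least one sprint")
  if (length(delta_schedule) != n)
    stop("`delta_schedule` length must equal the number of sprints")
  if (artifact_amp > 0 && artifact_freq <= 0.2)
    stop("`artifact_freq` must lie above the 0.2 Hz analysis cutoff")
  if (is.null(o2hb_schedule)) {
    thb <- rep_len(thb_schedule, n)
    o2hb_schedule <- delta_schedule - thb
  }
  if (length(o2hb_schedule) != n)
    stop("`o2hb_schedule` length must equal the number of sprints")
  if (is.null(tsi_drop_schedule))
    tsi_drop_schedule <- 0.8 * delta_schedule
  tsi_drop_schedule <- rep_len(tsi_drop_schedule, n)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  dt <- 1 / fs
  total_s <- max(timeline$recovery_end) + tail_s
  t <- seq(0, total_s - dt, by = dt)

  # C1 piecewise raised-cosine state: rise by amp during each sprint,
  # relax `recover_frac` of it during the recovery, zero slope at every
  # boundary. Amplitudes are scaled so the sampled per-sprint max-min
  # (last sample strictly before `end`) equals the schedule entry exactly.
  build <- function(amp_schedule, sign = 1) {
    x <- numeric(length(t))
    v <- 0
    seg_start <- 0
    for (k in seq_len(n)) {
      s0 <- timeline$start[k]; s1 <- timeline$end[k]
      r1 <- timeline$recovery_end[k]
      idx <- which(t >= seg_start - 1e-9 & t < s0 - 1e-9)
      x[idx] <- v
      d <- s1 - s0
      span <- (ceiling(s1 * fs - 1e-9) - 1) / fs - s0  # sampled span
      amp <- sign * amp_schedule[k] / ((1 - cos(pi * span / d)) / 2)
      idx <- which(t >= s0 - 1e-9 & t < s1 - 1e-9)
      x[idx] <- v + amp * (1 - cos(pi * (t[idx] - s0) / d)) / 2
      v_top <- v + amp
      rec <- recover_frac * amp
      dr <- r1 - s1
      idx <- which(t >= s1 - 1e-9 & t < r1 - 1e-9)
      x[idx] <- v_top - rec * (1 - cos(pi * (t[idx] - s1) / dr)) / 2
      v <- v_top - rec
      seg_start <- r1
    }
    idx <- which(t >= seg_start - 1e-9)
    x[idx] <- v
    x
  }
  hhb_clean <- build(delta_schedule, sign = 1)
  o2hb_clean <- build(o2hb_schedule, sign = -1)
  tsi_clean <- tsi_baseline + build(tsi_drop_schedule, sign = -1)

  noisy <- function(clean) {
    x <- clean + drift * t / 60
    if (artifact_amp > 0) x <- x + artifact_amp * sin(2 * pi * artifact_freq * t)
    if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
    x
  }
  mk <- function(clean, channel, units) {
    tr <- channel_trace(noisy(clean), fs, channel = channel, units = units,
                       site = site)
    attr(tr, "clean") <- clean
    tr
  }
  o2hb <- mk(o2hb_clean, "O2Hb", "uM")
  hhb <- mk(hhb_clean, "HHb", "uM")
  tsi <- mk(tsi_clean, "TSI", "%")
  clean_delta <- function(x) vapply(seq_len(n), function(k) {
    idx <- which(t >= timeline$start[k] - 1e-9 & t < timeline$end[k] - 1e-9)
    max(x[idx]) - min(x[idx])
  }, numeric(1))
  clean_max <- function(x) vapply(seq_len(n), function(k) {
    idx <- which(t >= timeline$start[k] - 1e-9 & t < timeline$end[k] - 1e-9)
    max(x[idx])
  }, numeric(1))
  list(o2hb = o2hb, hhb = hhb, tsi = tsi,
       truth = list(delta_hhb = clean_delta(hhb_clean),
                    delta_o2hb = clean_delta(o2hb_clean),
                    delta_thb = clean_delta(o2hb_clean + hhb_clean),
                    tsi_max = clean_max(tsi_clean),
                    delta_tsi = clean_delta(tsi_clean)))
}
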