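# Study-level synthetic data: participants x occlusion conditions with known
# endpoint ground truth, full signal traces, and effect-size presets.

#' Default protocol configuration
#'
#' Protocol constants of the repeated-sprint test: 10-s all-out sprints with
#' 20-s active recovery until task failure (cadence below 70 rpm), two
#' warm-up sprints, occlusion conditions at 0/45/60 % of the resting
#' pulse-elimination pressure, and per-channel sampling rates.
#'
#' @return A named list with protocol fields.
#' @export
default_protocol <- function() {
  list(
    sprint_duration_s = 10,
    recovery_duration_s = 20,
    warmup_sprints = 2L,
    cadence_failure_rpm = 70,
    conditions = c(0, 45, 60),
    fs = list(power = 10, cadence = 10, nirs = 10, force = 1000,
              emg = 2000, hr = 1, spo2 = 0.2)
  )
}

#' Default condition effect-size presets
#'
#' Endpoint-level generating parameters for the synthetic study: baseline
#' group means, between-participant SDs, residual SDs, and per-condition
#' effects (multiplicative for performance endpoints, additive for voluntary
#' activation). The presets are patterned after group statistics typical of
#' repeated-sprint testing under blood flow restriction — e.g. sprint count
#' dropping by roughly 47 % at 45 % occlusion and 66 % at 60 % — and are
#' generating presets for validation, not reproduced estimates.
#'
#' @return Nested named list, one entry per endpoint.
#' @export
default_effect_sizes <- function() {
  list(
    n_sprints = list(baseline = 29.8, participant_sd = 12, residual_sd = 3,
                     mult = c(`0` = 1, `45` = 0.526, `60` = 0.342)),
    peak_power = list(baseline = 680, participant_sd = 120, residual_sd = 15,
                      mult = c(`0` = 1, `45` = 0.95, `60` = 0.98)),
    decrement_rate = list(values = c(`0` = 0.022, `45` = 0.055, `60` = 0.075)),
    hhb_delta = list(baseline = 10, participant_sd = 2, residual_sd = 0.5,
                     mult = c(`0` = 1, `45` = 0.85, `60` = 0.65),
                     set_trend = -0.30),
    thb_delta = list(values = c(`0` = 2, `45` = 4.5, `60` = 5.5)),
    mvc_pre = list(baseline = 270, participant_sd = 120, residual_sd = 10),
    mvc_post_ratio = list(values = c(`0` = 0.91, `45` = 0.75, `60` = 0.52)),
    val_pre = list(baseline = 86, participant_sd = 8, residual_sd = 2),
    val_post_delta = list(values = c(`0` = 2, `45` = -5, `60` = -14)),
    p100_pre = list(baseline = 60, participant_sd = 15, residual_sd = 2),
    p100_post_ratio = list(values = c(`0` = 0.85, `45` = 0.85, `60` = 0.8)),
    p10_over_p100_pre = list(values = c(`0` = 0.91, `45` = 0.92, `60` = 0.90)),
    p10_over_p100_post = list(values = c(`0` = 0.63, `45` = 0.68, `60` = 0.63)),
    emg_rms = list(baseline = 0.1475, participant_sd = 0.03,
                   residual_sd = 0.005),
    m_wave_pp = list(values = c(`0` = 2.5, `45` = 2.5, `60` = 2.5)),
    vo2_peak = list(baseline = 2.72, participant_sd = 0.5, residual_sd = 0.1,
                    mult = c(`0` = 1, `45` = 0.864, `60` = 0.818)),
    hr_max = list(baseline = 185, participant_sd = 8, residual_sd = 3,
                  mult = c(`0` = 1, `45` = 0.957, `60` = 0.924)),
    spo2 = list(baseline = 93.8, participant_sd = 3, residual_sd = 1,
                mult = c(`0` = 1, `45` = 0.966, `60` = 0.98)),
    lactate = list(baseline = 9.5, participant_sd = 3, residual_sd = 1,
                   mult = c(`0` = 1, `45` = 0.76, `60` = 0.91)),
    rpe_legs = list(baseline = 17.7, participant_sd = 1, residual_sd = 0.5,
                    mult = c(`0` = 1, `45` = 1.10, `60` = 1.10)),
    rpe_breathing = list(baseline = 18.3, participant_sd = 1,
                         residual_sd = 0.5,
                         mult = c(`0` = 1, `45` = 0.97, `60` = 0.85))
  )
}

#' Simulate a balanced endpoint table with known effects
#'
#' Draws one endpoint value per participant x condition from a Gaussian
#' mixed-effects generating model: a participant random intercept (SD
#' `participant_sd`) added to the baseline, a condition effect applied
#' multiplicatively to the participant's own level (or additively when
#' `additive` is supplied), and residual noise. With all multipliers at 1
#' this is exactly the additive linear mixed model the inference stage
#' assumes, which is the regime used for type-I-error calibration.
#'
#' @param n_participants Number of participants (>= 2).
#' @param baseline Grand mean under the reference condition.
#' @param participant_sd SD of the participant random intercept.
#' @param residual_sd Residual SD.
#' @param mult Named vector of per-condition multipliers on `baseline`
#'   (names are condition labels). Ignored when `additive` is given.
#' @param additive Optional named vector of per-condition additive offsets.
#' @param seed Optional integer seed (local to this call).
#' @return Data frame with columns `participant`, `condition` (factors) and
#'   `value`, one row per cell.
#' @export
simulate_endpoints <- function(n_participants, baseline, participant_sd,
                               residual_sd,
                               mult = c(`0` = 1, `45` = 1, `60` = 1),
                               additive = NULL, seed = NULL) {
  if (n_participants < 2L) stop("`n_participants` must be >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  conds <- names(if (is.null(additive)) mult else additive)
  u <- rnorm(n_participants, 0, participant_sd)
  out <- expand.grid(participant = factor(seq_len(n_participants)),
                     condition = factor(conds, levels = conds),
                     KEEP.OUT.ATTRS = FALSE)
  lvl <- baseline + u[out$participant]
  out$value <- if (is.null(additive)) {
    lvl * as.numeric(mult[as.character(out$condition)])
  } else {
    lvl + as.numeric(additive[as.character(out$condition)])
  }
  out$value <- out$value + rnorm(nrow(out), 0, residual_sd)
  out
}

# One sub-seed per participant x condition x channel group, derived from the
# study seed; keeps every draw reproducible and independent of ordering.
sub_seed <- function(seed, i, j, k = 0L) {
  (seed * 7919L + i * 1009L + j * 101L + k * 17L) %% 2147483647L
}

#' Generate a complete synthetic study
#'
#' Generates a full repeated-sprint study: `n_participants` participants,
#' each tested under every occlusion condition, with ergometer, NIRS
#' (muscle and cerebral), neuromuscular (pre and post), gas-exchange, heart
#' rate and pulse-oximetry channels, plus scalar endpoints and a ground
#' truth table holding every injected value. Endpoint-level truth is drawn
#' first from [simulate_endpoints()]-style models defined by
#' `effect_sizes`; signal traces are then synthesised to embody those
#' values, with the study-level `noise` settings. Identical seeds give
#' bit-identical studies.
#'
#' @param n_participants Number of participants (default 11).
#' @param effect_sizes Endpoint presets, see [default_effect_sizes()].
#' @param protocol Protocol constants, see [default_protocol()].
#' @param noise Named list: `power_sd` (W), `nirs_artifact_amp` (uM),
#'   `nirs_artifact_freq` (Hz), `nirs_sd` (uM), `force_sd` (N),
#'   `emg_sd` (mV).
#' @param seed Integer seed for the whole study.
#' @param signals Generate full signal traces (`TRUE`) or endpoint truth
#'   only (`FALSE`, much faster; used for statistical calibration).
#' @return An object of class `bfr_study`: list with `participants`,
#'   `conditions`, `cells` (nested list `[[participant]][[condition]]`),
#'   and `truth` (data frame of injected endpoint values).
#' @export
generate_study <- function(n_participants = 11,
                           effect_sizes = default_effect_sizes(),
                           protocol = default_protocol(),
                           noise = list(power_sd = 15,
                                        nirs_artifact_amp = 3,
                                        nirs_artifact_freq = 1.4,
                                        nirs_sd = 0.2,
                                        force_sd = 0.5,
                                        emg_sd = 0.005),
                           seed = 1, signals = TRUE) {
  if (n_participants < 2L) stop("`n_participants` must be >= 2")
  es <- effect_sizes
  conds <- protocol$conditions
  cond_lab <- as.character(conds)

  draw <- function(spec, i, cond, k) {
    # one endpoint value for participant i under `cond`
    set.seed(sub_seed(seed, i, match(cond, conds), k))
    if (!is.null(spec$values)) return(spec$values[[as.character(cond)]])
    u <- attr(spec, "u")
    base <- spec$baseline
    m <- if (!is.null(spec$mult)) spec$mult[[as.character(cond)]] else 1
    # condition effect scales the participant's own level, so per-subject
    # percent changes centre on 1 - m
    (base + u[i]) * m + rnorm(1, 0, spec$residual_sd)
  }
  # participant random intercepts per endpoint (shared across conditions)
  set.seed(sub_seed(seed, 0L, 0L, 1L))
  for (nm in names(es)) {
    if (!is.null(es[[nm]]$participant_sd))
      attr(es[[nm]], "u") <- rnorm(n_participants, 0, es[[nm]]$participant_sd)
  }

  truth <- list()
  cells <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    cells[[i]] <- setNames(vector("list", length(conds)), cond_lab)
    for (j in seq_along(conds)) {
      cond <- conds[j]
      ns <- max(2L, round(draw(es$n_sprints, i, cond, 2L)))
      peak <- max(100, draw(es$peak_power, i, cond, 3L))
      dec <- es$decrement_rate$values[[cond_lab[j]]]
      hhb0 <- max(1, draw(es$hhb_delta, i, cond, 4L))
      thb <- es$thb_delta$values[[cond_lab[j]]]
      trend <- es$hhb_delta$set_trend
      hhb_sched <- hhb0 * (1 + trend * (seq_len(ns) - 1) / max(1, ns - 1))
      mvc_pre <- max(50, draw(es$mvc_pre, i, cond, 5L))
      mvc_post <- mvc_pre * es$mvc_post_ratio$values[[cond_lab[j]]]
      val_pre <- min(100, max(0, draw(es$val_pre, i, cond, 6L)))
      val_post <- min(100, max(0, val_pre +
                                 es$val_post_delta$values[[cond_lab[j]]]))
      p100_pre <- max(10, draw(es$p100_pre, i, cond, 7L))
      p100_post <- p100_pre * es$p100_post_ratio$values[[cond_lab[j]]]
      p10_pre <- p100_pre * es$p10_over_p100_pre$values[[cond_lab[j]]]
      p10_post <- p100_post * es$p10_over_p100_post$values[[cond_lab[j]]]
      emg_rms_pre <- max(0.01, draw(es$emg_rms, i, cond, 8L))
      emg_rms_post <- emg_rms_pre *
        es$mvc_post_ratio$values[[cond_lab[j]]]  # drive drops with force
      mwave <- es$m_wave_pp$values[[cond_lab[j]]]
      vo2 <- max(0.5, draw(es$vo2_peak, i, cond, 9L))
      hrmax <- min(200, draw(es$hr_max, i, cond, 10L))
      spo2 <- min(99, draw(es$spo2, i, cond, 11L))
      lactate <- max(1, draw(es$lactate, i, cond, 12L))
      rpe_l <- min(20, draw(es$rpe_legs, i, cond, 13L))
      rpe_b <- min(20, draw(es$rpe_breathing, i, cond, 14L))

      truth[[length(truth) + 1L]] <- data.frame(
        participant = i, condition = cond, n_sprints = ns,
        peak_power = peak, decrement_rate = dec,
        hhb_delta_first = hhb_sched[1], thb_delta = thb,
        mvc_pre = mvc_pre, mvc_post = mvc_post,
        val_pre = val_pre, val_post = val_post,
        p100_pre = p100_pre, p100_post = p100_post,
        p10_pre = p10_pre, p10_post = p10_post,
        emg_rms_pre = emg_rms_pre, emg_rms_post = emg_rms_post,
        m_wave_pp = mwave, vo2_peak = vo2, hr_max = hrmax,
        spo2 = spo2, lactate = lactate,
        rpe_legs = rpe_l, rpe_breathing = rpe_b
      )

      cell <- list(truth = truth[[length(truth)]])
      if (signals) {
        rst <- generate_power_profile(
          ns, peak_power = peak, decrement_rate = dec,
          noise_sd = noise$power_sd, seed = sub_seed(seed, i, j, 20L),
          fs = protocol$fs$power,
          sprint_duration_s = protocol$sprint_duration_s,
          recovery_duration_s = protocol$recovery_duration_s)
        nirs_m <- generate_nirs_traces(
          rst$timeline, site = "vastus_lateralis",
          delta_schedule = hhb_sched, thb_schedule = thb,
          artifact_freq = noise$nirs_artifact_freq,
          artifact_amp = noise$nirs_artifact_amp,
          noise_sd = noise$nirs_sd, seed = sub_seed(seed, i, j, 21L),
          fs = protocol$fs$nirs)
        nirs_c <- generate_nirs_traces(
          rst$timeline, site = "prefrontal_cortex",
          delta_schedule = 0.4 * hhb_sched,
          thb_schedule = 0.3 * thb, tsi_baseline = 72,
          artifact_freq = noise$nirs_artifact_freq,
          artifact_amp = 0.3 * noise$nirs_artifact_amp,
          noise_sd = noise$nirs_sd, seed = sub_seed(seed, i, j, 22L),
          fs = protocol$fs$nirs)
        nm_pre <- generate_neuromuscular_traces(
          mvc_true = mvc_pre, val_true = val_pre, p100 = p100_pre,
          p10 = p10_pre, twitch = 0.5 * p100_pre, emg_rms = emg_rms_pre,
          m_wave_pp = mwave, noise_sd = noise$force_sd,
          emg_noise_sd = noise$emg_sd, seed = sub_seed(seed, i, j, 23L),
          fs_force = protocol$fs$force, fs_emg = protocol$fs$emg)
        nm_post <- generate_neuromuscular_traces(
          mvc_true = mvc_post, val_true = val_post, p100 = p100_post,
          p10 = p10_post, twitch = 0.5 * p100_post, emg_rms = emg_rms_post,
          m_wave_pp = mwave, noise_sd = noise$force_sd,
          emg_noise_sd = noise$emg_sd, seed = sub_seed(seed, i, j, 24L),
          fs_force = protocol$fs$force, fs_emg = protocol$fs$emg)
        dur <- max(rst$timeline$recovery_end)
        set.seed(sub_seed(seed, i, j, 25L))
        # breath-by-breath oxygen uptake rising toward the injected peak
        bt <- cumsum(runif(ceiling(dur / 0.6), 0.5, 1.3))
        bt <- bt[bt < dur]
        vo2_vals <- vo2 * (0.3 + 0.7 * (1 - exp(-bt / 60))) +
          rnorm(length(bt), 0, 0.03 * vo2)
        hr_t <- seq(0, dur - 1, by = 1 / protocol$fs$hr)
        hr_vals <- hrmax - (hrmax - 80) * exp(-hr_t / 90) +
          rnorm(length(hr_t), 0, 1.5)
        sp_t <- seq(0, dur - 1 / protocol$fs$spo2, by = 1 / protocol$fs$spo2)
        sp_vals <- pmin(99, 98 - (98 - spo2) * (sp_t / max(sp_t))) +
          rnorm(length(sp_t), 0, 0.2)
        cell <- c(cell, list(
          power = rst$power, cadence = rst$cadence,
          timeline = rst$timeline, power_truth = rst$truth,
          nirs_muscle = nirs_m, nirs_cerebral = nirs_c,
          nm_pre = nm_pre, nm_post = nm_post,
          vo2 = data.frame(time_s = bt, value = vo2_vals),
          hr = channel_trace(hr_vals, protocol$fs$hr, "hr", "bpm"),
          spo2 = channel_trace(sp_vals, protocol$fs$spo2, "spo2", "%"),
          scalars = list(lactate = lactate, rpe_legs = rpe_l,
                         rpe_breathing = rpe_b)
        ))
      }
      cells[[i]][[cond_lab[j]]] <- cell
    }
  }
  structure(
    list(participants = seq_len(n_participants), conditions = conds,
         cells = cells, truth = do.call(rbind, truth),
         protocol = protocol, seed = seed),
    class = "bfr_study"
  )
}

#' @export
print.bfr_study <- function(x, ...) {
  cat(sprintf("<bfr_study> %d participants x %d conditions (%s), seed %d\n",
              length(x$participants), length(x$conditions),
              paste0(x$conditions, "%", collapse = "/"), x$seed))
  invisible(x)
}
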