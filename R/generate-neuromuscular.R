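# Synthetic neuromuscular assessment: evoked force, surface EMG and
# stimulation markers with exactly controllable ground truth.

# Twitch-like force transient: unit peak at t = tc after onset.
twitch_template <- function(t_rel, tc = 0.08) {
  out <- numeric(length(t_rel))
  pos <- t_rel >= 0
  out[pos] <- (t_rel[pos] / tc) * exp(1 - t_rel[pos] / tc)
  out
}

#' Generate a synthetic neuromuscular assessment recording
#'
#' Builds the force (1000 Hz) and EMG (2000 Hz) traces of one pre- or
#' post-test neuromuscular assessment: a maximal voluntary contraction (MVC)
#' with a superimposed doublet delivered on the plateau, followed at 2-s
#' spacing by resting evoked responses (100 Hz doublet P100, 10 Hz doublet
#' P10, single twitch). The superimposed increment is sized by inverting the
#' interpolated-twitch voluntary activation formula at the requested
#' `val_true`, with the potentiated resting doublet equal to `p100`; full
#' activation (`val_true = 100`) yields a zero increment. EMG during the MVC
#' is band-limited (20-450 Hz) Gaussian activity rescaled so its RMS over
#' the 250-ms epoch centred on peak voluntary force equals `emg_rms`
#' exactly, and the resting single twitch carries a biphasic M-wave scaled
#' to `m_wave_pp` peak-to-peak. Stimulation times are returned as markers.
#'
#' @param mvc_true Plateau voluntary force (N, > 0).
#' @param val_true Voluntary activation level in `[0, 100]` (%).
#' @param p100,p10,twitch Resting evoked amplitudes (N).
#' @param emg_rms Target EMG RMS over the 250-ms peak-force epoch (mV).
#' @param m_wave_pp Target M-wave peak-to-peak amplitude (mV).
#' @param noise_sd Gaussian noise SD added to the force trace (N).
#' @param emg_noise_sd Baseline EMG noise SD (mV).
#' @param seed Optional integer seed (local to this call).
#' @param fs_force,fs_emg Sampling rates (Hz).
#' @return A list with `force` and `emg` ([channel_trace()], each carrying a
#'   `"clean"` attribute), `markers` (data frame `label`, `time_s`), and
#'   `truth` (list of all injected parameter values, including the
#'   superimposed increment amplitude).
#' @export
generate_neuromuscular_traces <- function(mvc_true = 300, val_true = 85,
                                          p100 = 60, p10 = 54, twitch = 30,
                                          emg_rms = 0.15, m_wave_pp = 2.5,
                                          noise_sd = 0, emg_noise_sd = 0,
                                          seed = NULL,
                                          fs_force = 1000, fs_emg = 2000) {
  if (mvc_true <= 0) stop("`mvc_true` must be positive")
  if (val_true < 0 || val_true > 100)
    stop("`val_true` must lie in [0, 100]")
  if (any(c(p100, p10, twitch) < 0)) stop("evoked amplitudes must be >= 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  dur <- 12                      # s
  t_ramp0 <- 1; t_plateau0 <- 2  # ramp up 1 s, plateau from 2 s
  t_stim <- 4                    # superimposed doublet on plateau
  t_release0 <- 4.6; t_release1 <- 5
  t_p100 <- 6; t_p10 <- 8; t_tw <- 10

  tf <- seq(0, dur - 1 / fs_force, by = 1 / fs_force)
  vol <- numeric(length(tf))
  ramp <- tf >= t_ramp0 & tf < t_plateau0
  vol[ramp] <- mvc_true * 0.5 * (1 - cos(pi * (tf[ramp] - t_ramp0)))
  vol[tf >= t_plateau0 & tf < t_release0] <- mvc_true
  rel <- tf >= t_release0 & tf < t_release1
  vol[rel] <- mvc_true * (1 - (tf[rel] - t_release0) / (t_release1 - t_release0))

  # superimposed increment from the inverted activation formula
  # (voluntary force at stimulation equals the plateau, i.e. MVC)
  sup_amp <- (1 - val_true / 100) * p100
  force_clean <- vol +
    sup_amp * twitch_template(tf - t_stim) +
    p100 * twitch_template(tf - t_p100, tc = 0.09) +
    p10 * twitch_template(tf - t_p10, tc = 0.09) +
    twitch * twitch_template(tf - t_tw, tc = 0.08)
  force_vals <- force_clean
  if (noise_sd > 0) force_vals <- force_vals + rnorm(length(tf), 0, noise_sd)
  force <- channel_trace(force_vals, fs_force, channel = "force", units = "N")
  attr(force, "clean") <- force_clean

  te <- seq(0, dur - 1 / fs_emg, by = 1 / fs_emg)
  emg_clean <- numeric(length(te))
  act <- te >= t_ramp0 & te < t_release1
  raw <- rnorm(sum(act))
  bp <- signal::butter(4, c(20, 450) / (fs_emg / 2), type = "pass")
  raw <- as.numeric(signal::filter(bp$b, bp$a, raw))
  # exact RMS over the 250-ms epoch centred on peak voluntary force (t = 2 s)
  t_peak <- t_plateau0
  emg_act_t <- te[act]
  epoch <- emg_act_t >= t_peak - 0.125 & emg_act_t < t_peak + 0.125
  w <- raw[epoch] - mean(raw[epoch])
  scale <- if (sqrt(mean(w^2)) > 0) emg_rms / sqrt(mean(w^2)) else 0
  emg_clean[act] <- raw * scale
  # biphasic M-wave on the resting single twitch, exact peak-to-peak
  mw_rel <- te - t_tw
  mw <- exp(-((mw_rel - 0.006) / 0.002)^2) - 0.7 * exp(-((mw_rel - 0.013) / 0.003)^2)
  mw[mw_rel < 0 | mw_rel > 0.05] <- 0
  mw_pp <- max(mw) - min(mw)
  emg_clean <- emg_clean + mw * (m_wave_pp / mw_pp)
  emg_vals <- emg_clean
  if (emg_noise_sd > 0) emg_vals <- emg_vals + rnorm(length(te), 0, emg_noise_sd)
  emg <- channel_trace(emg_vals, fs_emg, channel = "emg", units = "mV",
                       site = "vastus_lateralis")
  attr(emg, "clean") <- emg_clean

  markers <- data.frame(
    label = c("superimposed", "p100", "p10", "twitch"),
    time_s = c(t_stim, t_p100, t_p10, t_tw)
  )
  list(force = force, emg = emg, markers = markers,
       truth = list(mvc = mvc_true, val = val_true, superimposed = sup_amp,
                    p100 = p100, p10 = p10, twitch = twitch,
                    emg_rms = emg_rms, m_wave_pp = m_wave_pp,
                    t_peak_force = t_peak))
}
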