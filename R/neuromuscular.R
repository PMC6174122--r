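# Evoked-force and EMG neuromuscular fatigue metrics: MVC, superimposed and
# resting evoked amplitudes, voluntary activation, low-frequency fatigue
# ratio, EMG RMS and M-wave normalisation.

#' Peak maximal voluntary contraction force
#'
#' Baseline-corrected maximum voluntary force within the MVC window, which
#' should end at the superimposed stimulation so the evoked increment is
#' excluded. Baseline is the mean force over `baseline_window`.
#'
#' @param force A force [channel_trace()] (N).
#' @param mvc_window Length-2 interval (s): search window, ending at the
#'   superimposed stimulation time.
#' @param baseline_window Length-2 interval (s) of resting force used for
#'   baseline correction; default the first 0.5 s of the trace.
#' @return List with `value` (N) and `time` (s) of the peak.
#' @export
mvc_peak <- function(force, mvc_window, baseline_window = c(0, 0.5)) {
  stopifnot(inherits(force, "channel_trace"))
  bidx <- interval_index(force, baseline_window[1], baseline_window[2])
  baseline <- if (length(bidx)) mean(force$values[bidx]) else 0
  idx <- interval_index(force, mvc_window[1], mvc_window[2])
  if (length(idx) == 0L) stop("MVC window contains no samples")
  v <- force$values[idx] - baseline
  i <- which.max(v)
  if (v[i] <= 0) warning("no positive voluntary force in the MVC window")
  list(value = v[i], time = (idx[i] - 1) / force$fs)
}

#' Amplitude of an evoked force response
#'
#' Peak force within `window_s` seconds after a stimulation marker minus the
#' pre-stimulus baseline (mean force over the 100 ms ending `gap_s` before
#' the marker; the gap keeps the baseline clean when the recorded marker
#' lags the actual stimulation by a few tens of ms). For the superimposed
#' doublet the pre-stimulus baseline is the voluntary force at stimulation
#' onset, so the same rule applies.
#'
#' @param force A force [channel_trace()] (N).
#' @param marker Stimulation time (s).
#' @param window_s Post-stimulus search window (s), default 0.5.
#' @param baseline_s Pre-stimulus baseline span (s), default 0.1.
#' @param gap_s Gap between the baseline window and the marker (s),
#'   default 0.05.
#' @return Evoked amplitude (N).
#' @export
evoked_amplitude <- function(force, marker, window_s = 0.5,
                             baseline_s = 0.1, gap_s = 0.05) {
  stopifnot(inherits(force, "channel_trace"))
  t_end <- (length(force$values) - 1) / force$fs
  if (marker < baseline_s + gap_s || marker > t_end)
    stop("stimulation marker lies outside the trace")
  bidx <- interval_index(force, marker - baseline_s - gap_s, marker - gap_s)
  widx <- interval_index(force, marker, marker + window_s)
  if (length(bidx) == 0L || length(widx) == 0L)
    stop("empty baseline or search window around the marker")
  max(force$values[widx]) - mean(force$values[bidx])
}

#' Voluntary activation level (interpolated-twitch technique)
#'
#' Corrected interpolated-twitch formula: the superimposed-doublet amplitude
#' is scaled by the ratio of the voluntary force at stimulation to the peak
#' MVC force (correcting for stimulations delivered slightly off the peak),
#' then expressed against the potentiated resting doublet:
#' `VAL = (1 - superimposed * (voluntary_at_stim / mvc) / resting_doublet) * 100`.
#' Set `corrected = FALSE` for the uncorrected classic form. Values above
#' 100 (a negative superimposed estimate from noise) are clamped to 100 with
#' a warning.
#'
#' @param superimposed Superimposed-doublet amplitude (N, >= 0).
#' @param voluntary_at_stim Voluntary force at stimulation onset (N).
#' @param mvc Peak MVC force (N, > 0).
#' @param resting_doublet Potentiated resting doublet amplitude (N, > 0).
#' @param corrected Apply the voluntary/MVC correction (default `TRUE`).
#' @return Voluntary activation (%), in `[0, 100]`.
#' @export
#' @examples
#' compute_val(9, 300, 300, 60)   # 85
#' compute_val(9, 270, 300, 60)   # 86.5
compute_val <- function(superimposed, voluntary_at_stim, mvc,
                        resting_doublet, corrected = TRUE) {
  if (resting_doublet <= 0)
    stop("voluntary activation undefined: resting doublet must be positive")
  if (mvc <= 0) stop("`mvc` must be positive")
  if (voluntary_at_stim < 0 || voluntary_at_stim > mvc + 1e-9)
    stop("`voluntary_at_stim` must lie in [0, mvc]")
  corr <- if (corrected) voluntary_at_stim / mvc else 1
  val <- (1 - superimposed * corr / resting_doublet) * 100
  if (val > 100) {
    warning("voluntary activation above 100% (negative superimposed estimate); clamped")
    val <- 100
  }
  if (val < 0) {
    warning("voluntary activation below 0%; clamped")
    val <- 0
  }
  val
}

#' Low- to high-frequency evoked force ratio
#'
#' `P10 / P100`, the ratio of evoked force at 10 Hz versus 100 Hz paired
#' stimulation; a marker of low-frequency (peripheral) fatigue.
#'
#' @param p10,p100 Evoked amplitudes (N); `p100` must be positive.
#' @return The ratio.
#' @export
p10_over_p100 <- function(p10, p100) {
  if (p100 <= 0) stop("P10/P100 undefined: P100 must be positive")
  p10 / p100
}

#' EMG root mean square over the peak-force epoch
#'
#' RMS of the baseline-corrected (mean-subtracted) EMG over a 250-ms epoch
#' centred on the time of peak force during the MVC.
#'
#' @param emg An EMG [channel_trace()] (mV).
#' @param peak_time Time of peak MVC force (s).
#' @param epoch_s Epoch length (s), default 0.250.
#' @return RMS amplitude (mV).
#' @export
emg_rms_at_peak <- function(emg, peak_time, epoch_s = 0.250) {
  stopifnot(inherits(emg, "channel_trace"))
  idx <- interval_index(emg, peak_time - epoch_s / 2, peak_time + epoch_s / 2)
  if (length(idx) == 0L) stop("EMG epoch contains no samples")
  v <- emg$values[idx]
  v <- v - mean(v)
  sqrt(mean(v^2))
}

#' M-wave peak-to-peak amplitude
#'
#' Peak-to-peak amplitude of the evoked compound muscle action potential
#' within `window_s` seconds after the stimulation marker.
#'
#' @param emg An EMG [channel_trace()] (mV).
#' @param stim_marker Stimulation time (s).
#' @param window_s Post-stimulus window (s), default 0.05.
#' @return Peak-to-peak amplitude (mV); 0 with a warning if no deflection.
#' @export
m_wave_amplitude <- function(emg, stim_marker, window_s = 0.05) {
  stopifnot(inherits(emg, "channel_trace"))
  idx <- interval_index(emg, stim_marker, stim_marker + window_s)
  if (length(idx) == 0L) stop("M-wave window contains no samples")
  v <- emg$values[idx]
  pp <- max(v) - min(v)
  if (pp == 0) warning("no M-wave deflection after the stimulation")
  pp
}

#' Normalised EMG amplitude
#'
#' Voluntary EMG RMS divided by the M-wave peak-to-peak amplitude, removing
#' peripheral transmission/geometry influences from the voluntary signal.
#'
#' @param rms EMG RMS (mV).
#' @param m_wave_pp M-wave peak-to-peak amplitude (mV, > 0).
#' @return The ratio.
#' @export
rms_over_mwave <- function(rms, m_wave_pp) {
  if (m_wave_pp <= 0) stop("RMS/M-wave undefined: M-wave amplitude must be positive")
  rms / m_wave_pp
}

#' Full neuromuscular assessment of one recording
#'
#' Runs the complete extraction on one pre- or post-test recording: MVC
#' peak, superimposed-doublet amplitude, resting evoked amplitudes (P100,
#' P10, single twitch), voluntary activation (potentiated resting doublet =
#' resting P100), P10/P100, EMG RMS at peak force, M-wave amplitude (from
#' the resting single twitch), and RMS/M-wave.
#'
#' @param force,emg [channel_trace()] objects of the assessment.
#' @param markers Data frame with `label`
#'   (`"superimposed"`, `"p100"`, `"p10"`, `"twitch"`) and `time_s`.
#' @param phase `"pre"` or `"post"` (carried through).
#' @return One-row data frame of class `nm_assessment`.
#' @export
analyze_neuromuscular <- function(force, emg, markers,
                                  phase = c("pre", "post")) {
  phase <- match.arg(phase)
  mt <- function(lbl) {
    t <- markers$time_s[markers$label == lbl]
    if (length(t) != 1L) stop(sprintf("need exactly one '%s' marker", lbl))
    t
  }
  t_sup <- mt("superimposed")
  mvc <- mvc_peak(force, mvc_window = c(0, t_sup))
  bidx <- interval_index(force, 0, 0.5)
  rest <- if (length(bidx)) mean(force$values[bidx]) else 0
  vol_idx <- interval_index(force, t_sup - 0.1, t_sup)
  voluntary_at_stim <- mean(force$values[vol_idx]) - rest
  sup <- evoked_amplitude(force, t_sup)
  p100 <- evoked_amplitude(force, mt("p100"))
  p10 <- evoked_amplitude(force, mt("p10"))
  tw <- evoked_amplitude(force, mt("twitch"))
  val <- compute_val(sup, min(voluntary_at_stim, mvc$value), mvc$value, p100)
  rms <- emg_rms_at_peak(emg, mvc$time)
  mw <- m_wave_amplitude(emg, mt("twitch"))
  out <- data.frame(
    phase = phase, mvc_n = mvc$value, superimposed_n = sup,
    p100_n = p100, p10_n = p10, twitch_n = tw,
    val_pct = val, p10_over_p100 = p10_over_p100(p10, p100),
    emg_rms_mv = rms, m_wave_pp_mv = mw,
    rms_over_mwave = rms_over_mwave(rms, mw)
  )
  class(out) <- c("nm_assessment", "data.frame")
  out
}
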