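# Shared fixtures, built in code at test time.

# A small noise-free repeated-sprint test with NIRS channels.
make_clean_rst <- function(n_sprints = 5, deltas = c(10, 9, 8, 7, 6),
                           peak_power = 600, decrement_rate = 0.1) {
  rst <- generate_power_profile(n_sprints, peak_power = peak_power,
                                decrement_rate = decrement_rate,
                                noise_sd = 0)
  nirs <- generate_nirs_traces(rst$timeline, delta_schedule = deltas)
  c(rst, list(nirs = nirs))
}

# Analytic squared-magnitude response of one digital Butterworth pass,
# evaluated from the filter polynomials (independent of the filtering path).
butter_mag2 <- function(f_hz, fs, cutoff = 0.2, order = 4L) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * f_hz / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

# Brute-force peak 30-s window average of a breath-by-breath step function.
vo2_peak_bruteforce <- function(time_s, vo2, window_s = 30) {
  n <- length(time_s)
  best <- -Inf
  for (i in seq_len(n)) {
    a <- time_s[i]; b <- a + window_s
    if (b > time_s[n] + 1e-9) break
    tot <- 0
    for (j in seq_len(n - 1)) {
      lo <- max(a, time_s[j]); hi <- min(b, time_s[j + 1])
      if (hi > lo) tot <- tot + vo2[j] * (hi - lo)
    }
    best <- max(best, tot / window_s)
  }
  best
}
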