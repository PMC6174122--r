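#' Uniformly sampled physiological signal
#'
#' Lightweight container for one channel of a recording: a numeric vector of
#' samples together with its sampling rate and channel metadata. Time is
#' implicit: sample `i` is at `(i - 1) / fs` seconds.
#'
#' @param values Numeric vector of samples. Must be finite.
#' @param fs Sampling rate in Hz.
#' @param channel Channel name, e.g. `"power"`, `"O2Hb"`, `"HHb"`, `"TSI"`,
#'   `"force"`, `"emg"`.
#' @param units Unit string carried through for reporting (`"W"`, `"uM"`,
#'   `"%"`, `"N"`, `"mV"`, ...).
#' @param site Measurement site, e.g. `"vastus_lateralis"` or
#'   `"prefrontal_cortex"`.
#'
#' @return An object of class `channel_trace`.
#' @export
#' @examples
#' tr <- channel_trace(sin(seq(0, 10, by = 0.1)), fs = 10, channel = "HHb",
#'                     units = "uM", site = "vastus_lateralis")
#' trace_time(tr)[1:3]
channel_trace <- function(values, fs, channel = "signal", units = "",
                          site = "") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         channel = channel, units = units, site = site),
    class = "channel_trace"
  )
}

#' @export
print.channel_trace <- function(x, ...) {
  cat(sprintf("<channel_trace> %s%s: %d samples @ %g Hz (%.1f s)%s\n",
              x$channel,
              if (nzchar(x$site)) paste0(" [", x$site, "]") else "",
              length(x$values), x$fs, length(x$values) / x$fs,
              if (nzchar(x$units)) paste0(", units ", x$units) else ""))
  invisible(x)
}

#' @rdname channel_trace
#' @param trace A `channel_trace`.
#' @return `trace_time()`: the vector of sample times in seconds.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "channel_trace"))
  (seq_along(trace$values) - 1) / trace$fs
}

#' Ordered sprint/recovery intervals of one repeated-sprint test
#'
#' Holds the temporal structure of a repeated-sprint test: for each sprint its
#' start and end time, and the end of the recovery period that follows. All
#' per-sprint windows in this package are half-open, `[start, end)`, so the
#' last sample of a sprint is never counted twice against the recovery.
#'
#' @param start,end Numeric vectors of sprint start/end times (s), increasing,
#'   non-overlapping.
#' @param recovery_end Optional vector of recovery end times (s); defaults to
#'   the next sprint's start (and `end` for the last sprint).
#'
#' @return A data frame of class `sprint_timeline` with columns `sprint`,
#'   `start`, `end`, `recovery_end`.
#' @export
#' @examples
#' sprint_timeline(start = c(30, 60), end = c(40, 70))
sprint_timeline <- function(start, end, recovery_end = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (n != length(end)) stop("`start` and `end` must have equal length")
  if (n == 0L) {
    out <- data.frame(sprint = integer(0), start = numeric(0),
                      end = numeric(0), recovery_end = numeric(0))
    class(out) <- c("sprint_timeline", "data.frame")
    return(out)
  }
  if (any(end <= start)) stop("each sprint must have end > start")
  if (n > 1L && any(start[-1L] < end[-n]))
    stop("sprint intervals must be ordered and non-overlapping")
  if (is.null(recovery_end))
    recovery_end <- c(start[-1L], end[n])
  if (length(recovery_end) != n || any(recovery_end < end))
    stop("`recovery_end` must have one entry >= end per sprint")
  out <- data.frame(sprint = seq_len(n), start = start, end = end,
                    recovery_end = as.numeric(recovery_end))
  class(out) <- c("sprint_timeline", "data.frame")
  out
}

#' @rdname sprint_timeline
#' @param timeline A `sprint_timeline`.
#' @return `n_sprints()`: the number of sprint intervals.
#' @export
n_sprints <- function(timeline) {
  stopifnot(inherits(timeline, "sprint_timeline"))
  nrow(timeline)
}

# Sample indices of a half-open window [start, end) on a trace's time grid.
interval_index <- function(trace, start, end) {
  i0 <- ceiling(start * trace$fs - 1e-9) + 1L
  i1 <- ceiling(end * trace$fs - 1e-9)  # last sample strictly before `end`
  i0 <- max(1L, as.integer(i0))
  i1 <- min(length(trace$values), as.integer(i1))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

# The stored noise-free component of a generated trace, if present.
clean_values <- function(trace) {
  cl <- attr(trace, "clean")
  if (is.null(cl)) trace$values else cl
}
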