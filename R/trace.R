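#' Pressure trace
#'
#' A uniformly sampled pressure time series for one mouthpiece cavity.
#' This is the universal signal currency of the package: every scoring,
#' calibration and simulation routine consumes or produces one.
#'
#' Sample `i` (1-based) is taken at time `t0 + (i - 1) / fs` seconds; the
#' trace is considered to span the half-open interval
#' `[t0, t0 + length(values) / fs)`.
#'
#' @param values numeric vector of pressure readings in kPa; must be finite
#'   and non-empty.
#' @param fs sampling rate in Hz (> 0). The device default is 50 Hz, which
#'   resolves the 1.5 s scored window into 75 samples so a one-sample
#'   truncation error stays below 1.5%.
#' @param channel which cavity the trace was read from, `"lip"` or
#'   `"tongue"`.
#' @param t0 start time in seconds (default 0).
#'
#' @return An object of class `pressure_trace`: a list with fields
#'   `values`, `fs`, `channel`, `t0`.
#' @examples
#' tr <- pressure_trace(rep(0.3, 100), fs = 50, channel = "tongue")
#' window_mean(tr, trace_window(0, 2))
#' @export
pressure_trace <- function(values, fs = 50, channel = c("lip", "tongue"),
                           t0 = 0) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a pressure trace needs at least one sample")
  }
  if (!all(is.finite(values))) {
    stop("pressure values must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("sampling rate fs must be a single positive number")
  }
  structure(
    list(values = values, fs = fs, channel = channel, t0 = t0),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> channel=%s  n=%d  fs=%g Hz  span=[%g, %g) s  range=[%.3g, %.3g] kPa\n",
    x$channel, length(x$values), x$fs, x$t0, trace_end(x),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
length.pressure_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param trace a [pressure_trace()].
#' @return numeric vector of per-sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' End time of a trace
#'
#' The exclusive end of the trace span, `t0 + n / fs`, so that a trace holds
#' exactly `fs * duration` samples.
#'
#' @param trace a [pressure_trace()].
#' @return time in seconds.
#' @export
trace_end <- function(trace) {
  trace$t0 + length(trace$values) / trace$fs
}

#' Time window
#'
#' A half-open time interval `[start, end)` used to select samples from a
#' trace. Half-open windows tile a schedule without double-counting samples
#' at cycle boundaries.
#'
#' @param start start time in seconds.
#' @param end end time in seconds; must exceed `start`.
#' @return An object of class `trace_window`.
#' @export
trace_window <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) || end <= start) {
    stop("window must satisfy end > start with finite bounds")
  }
  structure(list(start = start, end = end), class = "trace_window")
}

#' @export
print.trace_window <- function(x, ...) {
  cat(sprintf("<trace_window> [%g, %g) s\n", x$start, x$end))
  invisible(x)
}

#' Relative pressure band
#'
#' A target range expressed as a fraction of the participant's maximal
#' pressure Pmax, e.g. the tracking-task target band of 3%-5% of Pmax.
#' Band membership is checked inclusively at both edges.
#'
#' @param lo lower bound, fraction of Pmax in `[0, 1)`.
#' @param hi upper bound, fraction of Pmax in `(lo, 1]`.
#' @return An object of class `pressure_band`.
#' @export
pressure_band <- function(lo = 0.03, hi = 0.05) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("band must satisfy 0 <= lo < hi <= 1")
  }
  structure(list(lo = lo, hi = hi), class = "pressure_band")
}

# indices of samples falling in the half-open window [start, end)
window_sample_idx <- function(trace, w) {
  tt <- trace_times(trace)
  which(tt >= w$start & tt < w$end)
}

as_window <- function(w) {
  if (inherits(w, "trace_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(trace_window(w[1], w[2]))
  stop("expected a trace_window or a numeric (start, end) pair")
}

#' Mean pressure over a window
#'
#' Arithmetic mean of the samples whose timestamps fall in the half-open
#' window `[start, end)`. Used by the zero calibration to estimate the
#' unloaded baseline.
#'
#' @param trace a [pressure_trace()].
#' @param w a [trace_window()] (or a numeric `c(start, end)` pair); must
#'   overlap the trace span.
#' @return mean pressure in kPa.
#' @export
window_mean <- function(trace, w) {
  w <- as_window(w)
  idx <- window_sample_idx(trace, w)
  if (length(idx) == 0L) stop("window outside trace")
  mean(trace$values[idx])
}

#' Fraction of window time spent inside an absolute pressure band
#'
#' The per-sample time-in-range statistic behind every tracking-task score:
#' the share of samples in `[w.start, w.end)` whose pressure lies in
#' `[lo, hi]` kPa (inclusive at both edges).
#'
#' @param trace a [pressure_trace()].
#' @param w a [trace_window()]; must overlap the trace span.
#' @param band_abs numeric `c(lo, hi)` absolute band in kPa, `lo < hi`.
#' @return fraction in `[0, 1]`.
#' @export
fraction_in_band <- function(trace, w, band_abs) {
  w <- as_window(w)
  if (length(band_abs) != 2L || !(band_abs[1] < band_abs[2])) {
    stop("band_abs must be c(lo, hi) with lo < hi")
  }
  idx <- window_sample_idx(trace, w)
  if (length(idx) == 0L) stop("window outside trace")
  p <- trace$values[idx]
  mean(p >= band_abs[1] & p <= band_abs[2])
}

#' Fraction of window time spent at or above a threshold
#'
#' The breathing-task statistic: share of samples in the window with
#' pressure `>= threshold`.
#'
#' @inheritParams fraction_in_band
#' @param threshold pressure threshold in kPa.
#' @return fraction in `[0, 1]`.
#' @export
fraction_above <- function(trace, w, threshold) {
  w <- as_window(w)
  idx <- window_sample_idx(trace, w)
  if (length(idx) == 0L) stop("window outside trace")
  mean(trace$values[idx] >= threshold)
}

#' Subtract a constant offset from a trace
#'
#' Applies a zero-calibration correction: every sample is reduced by
#' `offset`; length, sampling rate and channel are preserved.
#'
#' @param trace a [pressure_trace()].
#' @param offset offset in kPa.
#' @return a corrected [pressure_trace()].
#' @export
apply_offset <- function(trace, offset) {
  trace$values <- trace$values - offset
  trace
}

#' Read / write a two-channel trace CSV
#'
#' The on-disk trace format is a UTF-8 CSV with header
#' `time_s,p_lip_kPa,p_tongue_kPa`, one row per sample at a fixed sampling
#' rate. `read_trace_csv()` returns both channels as `pressure_trace`
#' objects, inferring `fs` from the median time step.
#'
#' @param path file path.
#' @return `read_trace_csv()`: a list with elements `lip` and `tongue`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "p_lip_kPa", "p_tongue_kPa")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns time_s, p_lip_kPa, p_tongue_kPa")
  }
  if (nrow(df) < 2L) stop("trace CSV needs at least two samples")
  dt <- stats::median(diff(df$time_s))
  # snap the inferred rate: float noise in the time column must not shift
  # half-open window boundaries downstream
  fs <- round(1 / dt, 6)
  list(
    lip = pressure_trace(df$p_lip_kPa, fs = fs, channel = "lip",
                         t0 = df$time_s[1]),
    tongue = pressure_trace(df$p_tongue_kPa, fs = fs, channel = "tongue",
                            t0 = df$time_s[1])
  )
}

#' @rdname read_trace_csv
#' @param lip,tongue `pressure_trace` objects sharing `fs` and `t0`.
#' @export
write_trace_csv <- function(lip, tongue, path) {
  if (length(lip) != length(tongue) || lip$fs != tongue$fs) {
    stop("lip and tongue traces must share length and sampling rate")
  }
  df <- data.frame(
    time_s = trace_times(lip),
    p_lip_kPa = lip$values,
    p_tongue_kPa = tongue$values
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
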