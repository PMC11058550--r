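#' Calibration policy
#'
#' Parameters governing the two calibration procedures run at the start of
#' every session: the zero (baseline) calibration and the three-attempt
#' maximal-pressure calibration.
#'
#' The maximal-pressure rule: the participant develops maximal pressure and
#' releases, three times; if the largest absolute deviation of the attempt
#' peaks from their mean, divided by the mean, exceeds `max_rel_dev`
#' (device default 7.5%), the whole three-attempt round is repeated,
#' otherwise the mean becomes Pmax.
#'
#' @param n_attempts attempts per round (>= 2, default 3).
#' @param max_rel_dev maximal tolerated relative deviation (default 0.075).
#'   The boundary case `rel_dev == max_rel_dev` is accepted: a round is
#'   repeated only when the deviation is strictly greater.
#' @param max_rounds maximum rounds before giving up (default 5).
#' @param zero_window_s duration in seconds of the released-pressure epoch
#'   averaged by the zero calibration (default 2).
#' @param dev_stat how "absolute deviation" is summarised over a round:
#'   `"max"` (strictest reading, default) or `"mean"` absolute deviation.
#' @return An object of class `calibration_policy`.
#' @export
calibration_policy <- function(n_attempts = 3, max_rel_dev = 0.075,
                               max_rounds = 5, zero_window_s = 2,
                               dev_stat = c("max", "mean")) {
  dev_stat <- match.arg(dev_stat)
  if (n_attempts < 2) stop("n_attempts must be >= 2")
  if (!(max_rel_dev > 0 && max_rel_dev < 1)) {
    stop("max_rel_dev must lie in (0, 1)")
  }
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  if (zero_window_s <= 0) stop("zero_window_s must be positive")
  structure(
    list(n_attempts = n_attempts, max_rel_dev = max_rel_dev,
         max_rounds = max_rounds, zero_window_s = zero_window_s,
         dev_stat = dev_stat),
    class = "calibration_policy"
  )
}

#' Zero-offset calibration
#'
#' Estimates the unloaded cavity baseline as the mean pressure over the
#' final `zero_window_s` seconds of a released-pressure trace. The device
#' runs this twice at session start — once on mouthpiece insertion and once
#' after the two-minute warm-up game — because the silicone mouthpiece
#' warms toward thermal steady state over roughly a minute and drags the
#' baseline with it; the post-warm-up measurement is the authoritative one.
#'
#' @param trace a [pressure_trace()] recorded with lips/tongue released;
#'   must span at least `zero_window_s` seconds.
#' @param policy a [calibration_policy()].
#' @param timestamp seconds since session start, recorded for the log.
#' @return An object of class `zero_calibration` with fields `channel`,
#'   `offset` (kPa), `window_duration`, `timestamp`.
#' @export
compute_zero_offset <- function(trace, policy = calibration_policy(),
                                timestamp = NA_real_) {
  span <- length(trace) / trace$fs
  if (span < policy$zero_window_s) {
    stop("trace too short for zero-calibration window")
  }
  w <- trace_window(trace_end(trace) - policy$zero_window_s, trace_end(trace))
  structure(
    list(channel = trace$channel,
         offset = window_mean(trace, w),
         window_duration = policy$zero_window_s,
         timestamp = timestamp),
    class = "zero_calibration"
  )
}

#' Peak pressure of each marked attempt segment
#'
#' The session layer marks where each maximal-pressure attempt starts and
#' ends (the participant presses OK after releasing); this extracts the
#' per-segment maximum.
#'
#' @param trace a [pressure_trace()].
#' @param segments list of [trace_window()]s (or `c(start, end)` pairs),
#'   one per attempt.
#' @param n expected number of attempts.
#' @return numeric vector of `n` peak pressures in kPa.
#' @export
extract_attempt_peaks <- function(trace, segments, n = length(segments)) {
  if (length(segments) < n) stop("fewer attempt segments than required")
  vapply(segments[seq_len(n)], function(w) {
    idx <- window_sample_idx(trace, as_window(w))
    if (length(idx) == 0L) stop("attempt segment outside trace")
    max(trace$values[idx])
  }, numeric(1))
}

#' Evaluate one round of maximal-pressure attempts
#'
#' Applies the repeat rule to one round of attempt peaks: with mean `m`,
#' `rel_dev = max_i |peak_i - m| / m` (or the mean absolute deviation under
#' `dev_stat = "mean"`); the round is accepted iff
#' `rel_dev <= policy$max_rel_dev`, in which case `m` is the channel's
#' Pmax.
#'
#' @param peaks numeric vector of `policy$n_attempts` positive peak
#'   pressures (kPa).
#' @param policy a [calibration_policy()].
#' @param channel channel label carried into the record.
#' @param rounds_used bookkeeping field set by [run_max_calibration()].
#' @param attempt_history list of all rounds' peaks (bookkeeping).
#' @return An object of class `max_calibration` with fields `channel`,
#'   `attempts`, `mean` (Pmax when accepted), `rel_dev`, `accepted`,
#'   `rounds_used`, `attempt_history`.
#' @export
evaluate_max_attempts <- function(peaks, policy = calibration_policy(),
                                  channel = "tongue", rounds_used = 1L,
                                  attempt_history = list(peaks)) {
  if (length(peaks) != policy$n_attempts) {
    stop(sprintf("expected %d attempt peaks, got %d",
                 policy$n_attempts, length(peaks)))
  }
  if (any(peaks <= 0)) stop("no pressure developed")
  m <- mean(peaks)
  dev <- abs(peaks - m)
  rel_dev <- switch(policy$dev_stat, max = max(dev), mean = mean(dev)) / m
  structure(
    list(channel = channel, attempts = peaks, mean = m, rel_dev = rel_dev,
         accepted = rel_dev <= policy$max_rel_dev,
         rounds_used = as.integer(rounds_used),
         attempt_history = attempt_history),
    class = "max_calibration"
  )
}

#' @export
print.max_calibration <- function(x, ...) {
  cat(sprintf(
    "<max_calibration> %s: Pmax=%.3g kPa  rel_dev=%.3f  %s (%d round%s)\n",
    x$channel, x$mean, x$rel_dev,
    if (x$accepted) "accepted" else "NOT accepted",
    x$rounds_used, if (x$rounds_used > 1) "s" else ""
  ))
  invisible(x)
}

#' Run the maximal-pressure calibration loop
#'
#' Draws fresh rounds of attempt peaks from `attempt_source` and evaluates
#' each with [evaluate_max_attempts()] until a round is accepted or
#' `max_rounds` is reached. When all attempts are redone on a repeat, the
#' whole round is replaced (not just the outlying attempt). An exhausted
#' source or round budget yields the last round flagged `accepted = FALSE`
#' rather than an error, so the session layer can mark the session
#' incomplete.
#'
#' @param attempt_source either a list of peak vectors (one per round) or a
#'   function `function(round)` returning the round's peaks.
#' @param policy a [calibration_policy()].
#' @param channel channel label.
#' @return a `max_calibration`.
#' @export
run_max_calibration <- function(attempt_source,
                                policy = calibration_policy(),
                                channel = "tongue") {
  draw <- if (is.function(attempt_source)) {
    attempt_source
  } else {
    rounds <- attempt_source
    function(round) if (round <= length(rounds)) rounds[[round]] else NULL
  }
  history <- list()
  result <- NULL
  for (round in seq_len(policy$max_rounds)) {
    peaks <- draw(round)
    if (is.null(peaks)) break  # source exhausted: keep last (unaccepted) round
    history[[round]] <- peaks
    result <- evaluate_max_attempts(peaks, policy, channel,
                                    rounds_used = round,
                                    attempt_history = history)
    if (result$accepted) return(result)
  }
  if (is.null(result)) stop("attempt source yielded no rounds")
  result
}
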