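#' Tracking-task configuration
#'
#' The tongue and lip pressure-tracking tasks share one cycle structure:
#' 8 s of rest with pressure released, then the target box rises to a band
#' of 3%-5% of Pmax for 3 s. The first 1.5 s of the target phase let the
#' participant react; only the final `target_s - react_s` seconds are
#' scored. Ten cycles make a 110 s task.
#'
#' @param n_cycles number of cycles (default 10).
#' @param rest_s rest-phase duration in seconds (default 8).
#' @param target_s target-phase duration in seconds (default 3).
#' @param react_s unscored reaction time at target onset (default 1.5);
#'   must be strictly less than `target_s`.
#' @param band a [pressure_band()], fractions of Pmax (default 3%-5%).
#' @param channel `"tongue"` or `"lip"`.
#' @return An object of class `tracking_task_config`.
#' @export
tracking_task_config <- function(n_cycles = 10, rest_s = 8, target_s = 3,
                                 react_s = 1.5, band = pressure_band(),
                                 channel = c("tongue", "lip")) {
  channel <- match.arg(channel)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (react_s >= target_s) {
    stop("react_s must be smaller than target_s (scored window empty)")
  }
  if (rest_s <= 0 || target_s <= 0 || react_s < 0) {
    stop("phase durations must be positive")
  }
  structure(
    list(n_cycles = n_cycles, rest_s = rest_s, target_s = target_s,
         react_s = react_s, band = band, channel = channel),
    class = "tracking_task_config"
  )
}

#' Breathing-task configuration
#'
#' The breathing task asks for a continuous small lip pressure of 4% of
#' Pmax while following a paced breathing pattern: 7 cycles of 8 s inhale
#' plus 8 s exhale (112 s). The guide pattern is display-only; the score is
#' the fraction of the whole task spent at or above the threshold.
#'
#' @param n_breaths breathing cycles (default 7).
#' @param inhale_s,exhale_s phase durations in seconds (default 8 each).
#' @param threshold_frac pressure threshold as a fraction of Pmax
#'   (default 0.04).
#' @return An object of class `breathing_task_config`.
#' @export
breathing_task_config <- function(n_breaths = 7, inhale_s = 8, exhale_s = 8,
                                  threshold_frac = 0.04) {
  if (n_breaths < 1) stop("n_breaths must be >= 1")
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("threshold_frac must lie in (0, 1)")
  }
  structure(
    list(n_breaths = n_breaths, inhale_s = inhale_s, exhale_s = exhale_s,
         threshold_frac = threshold_frac, channel = "lip"),
    class = "breathing_task_config"
  )
}

task_duration <- function(cfg) {
  if (inherits(cfg, "tracking_task_config")) {
    cfg$n_cycles * (cfg$rest_s + cfg$target_s)
  } else {
    cfg$n_breaths * (cfg$inhale_s + cfg$exhale_s)
  }
}

#' Build the per-cycle window schedule of a tracking task
#'
#' @param cfg a [tracking_task_config()].
#' @param t0 task start time in seconds (default 0).
#' @return A list with one element per cycle, each holding `rest`, `target`
#'   and `scored` [trace_window()]s. At the defaults, cycle k (0-based)
#'   occupies `[11k, 11k + 11)` with the scored window
#'   `[11k + 9.5, 11k + 11)`.
#' @export
build_tracking_schedule <- function(cfg = tracking_task_config(), t0 = 0) {
  cycle_s <- cfg$rest_s + cfg$target_s
  lapply(seq_len(cfg$n_cycles) - 1L, function(k) {
    start <- t0 + k * cycle_s
    list(
      rest = trace_window(start, start + cfg$rest_s),
      target = trace_window(start + cfg$rest_s, start + cycle_s),
      scored = trace_window(start + cfg$rest_s + cfg$react_s, start + cycle_s)
    )
  })
}

#' Score a pressure-tracking task
#'
#' For each cycle, computes the fraction of the scored window spent inside
#' the absolute band `[band$lo * Pmax, band$hi * Pmax]`; the task score is
#' 100 times the mean cycle fraction (cycles share a window length, so
#' this equals pooled in-band time over pooled scored time). Pressure
#' during rest and reaction phases never affects the score; the mean rest
#' pressure is logged per cycle for quality control.
#'
#' @param trace a [pressure_trace()] covering the full schedule.
#' @param cfg a [tracking_task_config()].
#' @param Pmax the channel's maximal pressure in kPa (> 0), from the
#'   session's accepted maximal-pressure calibration.
#' @param t0 task start time within the trace (default `trace$t0`).
#' @return An object of class `task_result`: fields `task_kind`,
#'   `score_pct` in \[0, 100\], `cycles` (data.frame with one row per cycle:
#'   `cycle`, `in_band_fraction`, `rest_mean_kPa`), `Pmax_used`.
#' @export
score_tracking_task <- function(trace, cfg = tracking_task_config(),
                                Pmax, t0 = trace$t0) {
  if (!is.numeric(Pmax) || Pmax <= 0) stop("Pmax must be positive")
  sched <- build_tracking_schedule(cfg, t0 = t0)
  if (trace_end(trace) < sched[[length(sched)]]$scored$end - 1e-9) {
    stop("trace shorter than the task schedule")
  }
  band_abs <- c(cfg$band$lo, cfg$band$hi) * Pmax
  fr <- vapply(sched, function(cy) fraction_in_band(trace, cy$scored, band_abs),
               numeric(1))
  rest_mean <- vapply(sched, function(cy) window_mean(trace, cy$rest),
                      numeric(1))
  structure(
    list(task_kind = cfg$channel,
         score_pct = 100 * mean(fr),
         cycles = data.frame(cycle = seq_along(fr),
                             in_band_fraction = fr,
                             rest_mean_kPa = rest_mean),
         Pmax_used = Pmax),
    class = "task_result"
  )
}

#' Score a breathing task
#'
#' The score is 100 times the fraction of the whole task window during
#' which lip pressure was at or above `threshold_frac * Pmax`.
#'
#' @param trace a lip [pressure_trace()] covering the task.
#' @param cfg a [breathing_task_config()].
#' @inheritParams score_tracking_task
#' @return a `task_result` with `task_kind = "breathing"` and no per-cycle
#'   breakdown.
#' @export
score_breathing_task <- function(trace, cfg = breathing_task_config(),
                                 Pmax, t0 = trace$t0) {
  if (!is.numeric(Pmax) || Pmax <= 0) stop("Pmax must be positive")
  dur <- task_duration(cfg)
  if (trace_end(trace) < t0 + dur - 1e-9) {
    stop("trace shorter than the task schedule")
  }
  frac <- fraction_above(trace, trace_window(t0, t0 + dur),
                         cfg$threshold_frac * Pmax)
  structure(
    list(task_kind = "breathing",
         score_pct = 100 * frac,
         cycles = data.frame(cycle = integer(), in_band_fraction = numeric(),
                             rest_mean_kPa = numeric()),
         Pmax_used = Pmax),
    class = "task_result"
  )
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s: score %.1f%% (Pmax %.3g kPa)\n",
              x$task_kind, x$score_pct, x$Pmax_used))
  invisible(x)
}
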