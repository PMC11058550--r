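#' Session configuration
#'
#' Timing and policy settings for one training session. The device default
#' session runs: zero calibration, a 2-minute warm-up game (letting the
#' mouthpiece reach thermal steady state), a second zero calibration, the
#' maximal-pressure calibration for tongue then lips, then four rounds of
#' [zero calibration, breathing task, lip task, tongue task, game]. At the
#' defaults the scheduled duration is about 34 minutes.
#'
#' @param rounds training rounds (default 4).
#' @param fs sampling rate in Hz (default 50).
#' @param warmup_s warm-up game duration in seconds (default 120).
#' @param game_s per-round game duration in seconds (default 120).
#' @param zero_cal_s released-pressure epoch per zero calibration
#'   (default 5; the calibration averages its final 2 s).
#' @param max_attempt_s nominal seconds per maximal-pressure attempt,
#'   used only for the session clock (default 10).
#' @param policy a [calibration_policy()].
#' @param thermal a [thermal_model()] for simulated sessions.
#' @param tracking,breathing task configurations (channel is overridden
#'   per step for tracking).
#' @param rules_by_variant named list of [game_rules()] per variant.
#' @param warmup_variant warm-up game (default `"paddle"`).
#' @param zero_cal_per_task if `TRUE`, a zero calibration precedes every
#'   task rather than every round.
#' @param start_date ISO date of training day 1, used for log timestamps.
#' @return An object of class `session_config`.
#' @export
session_config <- function(rounds = 4, fs = 50, warmup_s = 120, game_s = 120,
                           zero_cal_s = 5, max_attempt_s = 10,
                           policy = calibration_policy(),
                           thermal = thermal_model(),
                           tracking = tracking_task_config(),
                           breathing = breathing_task_config(),
                           rules_by_variant = NULL,
                           warmup_variant = "paddle",
                           zero_cal_per_task = FALSE,
                           start_date = "2024-01-01") {
  if (rounds < 1) stop("rounds must be >= 1")
  if (is.null(rules_by_variant)) {
    rules_by_variant <- lapply(
      c(paddle = "paddle", circle = "circle", missile = "missile",
        wall = "wall"),
      function(v) game_rules(v, fs = fs)
    )
  }
  structure(
    list(rounds = rounds, fs = fs, warmup_s = warmup_s, game_s = game_s,
         zero_cal_s = zero_cal_s, max_attempt_s = max_attempt_s,
         policy = policy, thermal = thermal, tracking = tracking,
         breathing = breathing, rules_by_variant = rules_by_variant,
         warmup_variant = warmup_variant,
         zero_cal_per_task = zero_cal_per_task, start_date = start_date),
    class = "session_config"
  )
}

#' Build the ordered step list of a session
#'
#' @param config a [session_config()].
#' @param seed seed for the (round-robin) game rotation order.
#' @return An object of class `session_plan`: a list of steps, each a list
#'   with `kind` (`"zero_cal"`, `"warmup_game"`, `"max_cal"`,
#'   `"breathing"`, `"lip_task"`, `"tongue_task"`, `"game"`) plus
#'   `channel`/`variant`/`duration_s` as applicable. A default plan holds
#'   4 breathing, 4 lip and 4 tongue tasks, 4 post-warm-up games, 6 zero
#'   calibrations and 2 maximal calibrations.
#' @export
build_session_plan <- function(config = session_config(), seed = 1L) {
  zc <- function() list(kind = "zero_cal", duration_s = config$zero_cal_s)
  steps <- list(
    zc(),
    list(kind = "warmup_game", variant = config$warmup_variant,
         duration_s = config$warmup_s),
    zc(),
    list(kind = "max_cal", channel = "tongue"),
    list(kind = "max_cal", channel = "lip")
  )
  variants <- names(config$rules_by_variant)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  order0 <- sample(variants)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  for (r in seq_len(config$rounds)) {
    round_steps <- list(
      zc(),
      list(kind = "breathing",
           duration_s = task_duration(config$breathing)),
      list(kind = "lip_task",
           duration_s = task_duration(config$tracking)),
      list(kind = "tongue_task",
           duration_s = task_duration(config$tracking)),
      list(kind = "game",
           variant = order0[(r - 1L) %% length(order0) + 1L],
           duration_s = config$game_s)
    )
    if (config$zero_cal_per_task) {
      round_steps <- append(round_steps, list(zc(), zc()), after = 2L)
    }
    steps <- c(steps, round_steps)
  }
  structure(list(steps = steps, rounds = config$rounds, seed = seed),
            class = "session_plan")
}

#' Scheduled duration of a plan, in seconds
#'
#' Sum of all step durations, counting each maximal calibration as
#' `n_attempts * max_attempt_s` for its first round.
#'
#' @param plan a [build_session_plan()] plan.
#' @param config the matching [session_config()].
#' @return seconds.
#' @export
plan_duration <- function(plan, config = session_config()) {
  sum(vapply(plan$steps, function(st) {
    if (st$kind == "max_cal") {
      config$policy$n_attempts * config$max_attempt_s
    } else {
      st$duration_s
    }
  }, numeric(1)))
}

#' Count step kinds in a plan
#'
#' @param plan a `session_plan`.
#' @return named integer vector of counts by `kind`.
#' @export
plan_counts <- function(plan) {
  kinds <- vapply(plan$steps, `[[`, character(1), "kind")
  table_int <- table(kinds)
  stats::setNames(as.integer(table_int), names(table_int))
}

# smooth pseudo-random game controller for simulated participants:
# band-limited sinusoidal lip/tongue pressure around half the game's
# reference deflection
make_play_controller <- function(ref_frac) {
  ph <- stats::runif(4, 0, 2 * pi)
  f <- stats::runif(4, 0.1, 0.5)
  function(t, state) {
    game_input(
      p_lip = ref_frac * 0.5 * (1 + sin(2 * pi * f[1] * t + ph[1]) *
                                  sin(2 * pi * f[2] * t + ph[2])),
      p_tongue = ref_frac * 0.5 * (1 + sin(2 * pi * f[3] * t + ph[3]) *
                                     sin(2 * pi * f[4] * t + ph[4]))
    )
  }
}

#' Run one simulated training session
#'
#' Executes a session plan end to end with traces supplied by a
#' [user_model()]: zero calibrations (the post-warm-up offset is the
#' authoritative correction for all scoring), maximal-pressure
#' calibration for both channels (its accepted mean is the Pmax used by
#' every task), then the alternating task/game rounds. Deterministic for
#' a fixed `(user, day, config, seed)`.
#'
#' If a maximal calibration is still unaccepted after the policy's round
#' budget the session is marked `completed = FALSE` with a reason; tasks
#' are still scored against a 1 kPa placeholder so the log stays complete.
#'
#' @param user a [user_model()].
#' @param day training day (1-28), drives the learning curve.
#' @param config a [session_config()].
#' @param seed RNG seed.
#' @param plan optionally a prebuilt [build_session_plan()] plan.
#' @return An object of class `session_record`.
#' @export
run_session <- function(user, day = 1L, config = session_config(),
                        seed = 1L, plan = NULL) {
  if (is.null(plan)) plan <- build_session_plan(config, seed = derive_seed(seed, 31L))
  set.seed(seed)
  clock <- 0
  offset <- c(lip = 0, tongue = 0)
  zero_cals <- list()
  max_cal <- list()
  tasks <- list()
  games <- list()
  reason <- NULL

  score_with <- function(channel) {
    if (!is.null(max_cal[[channel]]) && isTRUE(max_cal[[channel]]$accepted)) {
      max_cal[[channel]]$mean
    } else {
      1  # placeholder Pmax so an incomplete calibration still yields a log
    }
  }

  for (st in plan$steps) {
    kind <- st$kind
    if (kind == "zero_cal") {
      for (ch in c("lip", "tongue")) {
        tr <- generate_zero_trace(user, st$duration_s, Pmax = score_with(ch),
                                  thermal = config$thermal,
                                  session_t0 = clock, fs = config$fs,
                                  channel = ch)
        zc <- compute_zero_offset(tr, config$policy, timestamp = clock)
        zero_cals[[length(zero_cals) + 1L]] <- zc
        offset[[ch]] <- zc$offset
      }
      clock <- clock + st$duration_s
    } else if (kind %in% c("warmup_game", "game")) {
      rules <- config$rules_by_variant[[st$variant]]
      ctrl <- make_play_controller(rules$ref_frac)
      res <- run_game(rules, ctrl, duration_s = st$duration_s,
                      seed = derive_seed(seed, length(games) + 101L))
      games[[length(games) + 1L]] <- list(
        variant = res$variant, final_score = res$final_score,
        high_score = res$high_score, steps = res$steps,
        duration_s = res$duration_s, warmup = (kind == "warmup_game")
      )
      clock <- clock + st$duration_s
    } else if (kind == "max_cal") {
      ch <- st$channel
      mc <- tryCatch(
        run_max_calibration(function(round) generate_attempt_peaks(
          user, ch, config$policy$n_attempts),
          config$policy, channel = ch),
        error = function(e) {
          structure(list(channel = ch, attempts = numeric(0), mean = NA_real_,
                         rel_dev = NA_real_, accepted = FALSE,
                         rounds_used = 0L, attempt_history = list()),
                    class = "max_calibration")
        }
      )
      max_cal[[ch]] <- mc
      if (!mc$accepted) {
        reason <- paste0("max calibration not accepted (", ch, ")")
      }
      clock <- clock +
        mc$rounds_used * config$policy$n_attempts * config$max_attempt_s
    } else if (kind == "breathing") {
      Pm <- score_with("lip")
      tr <- generate_user_trace(user, config$breathing, day, Pm,
                                config$thermal, session_t0 = clock,
                                fs = config$fs)
      tr <- apply_offset(tr, offset[["lip"]])
      tasks[[length(tasks) + 1L]] <-
        score_breathing_task(tr, config$breathing, Pm)
      clock <- clock + st$duration_s
    } else if (kind %in% c("lip_task", "tongue_task")) {
      ch <- sub("_task$", "", kind)
      cfg_t <- config$tracking
      cfg_t$channel <- ch
      Pm <- score_with(ch)
      tr <- generate_user_trace(user, cfg_t, day, Pm, config$thermal,
                                session_t0 = clock, fs = config$fs)
      tr <- apply_offset(tr, offset[[ch]])
      tasks[[length(tasks) + 1L]] <- score_tracking_task(tr, cfg_t, Pm)
      clock <- clock + st$duration_s
    } else {
      stop("unknown step kind: ", kind)
    }
  }

  n_expected <- config$rounds * 3L
  completed <- length(tasks) == n_expected &&
    all(vapply(tasks, function(x) is.finite(x$score_pct), logical(1))) &&
    is.null(reason)
  stamp <- format(
    as.POSIXct(paste0(config$start_date, " 18:00:00"), tz = "UTC") +
      (day - 1) * 86400,
    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"
  )
  structure(
    list(schema_version = 1L, participant_id = user$id,
         day = as.integer(day), timestamp = stamp,
         completed = completed,
         reason = if (is.null(reason)) NA_character_ else reason,
         zero_cals = zero_cals, max_cal = max_cal, tasks = tasks,
         games = games, duration_s = clock, seed = as.integer(seed)),
    class = "session_record"
  )
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf(
    "<session_record> %s day %d: %s, %d tasks, %d games, %.1f min\n",
    x$participant_id, x$day,
    if (x$completed) "completed" else "incomplete",
    length(x$tasks), length(x$games), x$duration_s / 60
  ))
  invisible(x)
}

# ---- log (de)serialisation -------------------------------------------------

record_to_list <- function(x) {
  enc_zc <- function(z) list(channel = z$channel, offset = z$offset,
                             window_duration = z$window_duration,
                             timestamp = z$timestamp)
  enc_mc <- function(m) list(channel = m$channel,
                             attempts = as.numeric(m$attempts),
                             mean = m$mean, rel_dev = m$rel_dev,
                             accepted = m$accepted,
                             rounds_used = m$rounds_used,
                             attempt_history = lapply(m$attempt_history,
                                                      as.numeric))
  enc_task <- function(tk) list(
    task_kind = tk$task_kind, score_pct = tk$score_pct,
    cycles = list(cycle = as.integer(tk$cycles$cycle),
                  in_band_fraction = as.numeric(tk$cycles$in_band_fraction),
                  rest_mean_kPa = as.numeric(tk$cycles$rest_mean_kPa)),
    Pmax_used = tk$Pmax_used)
  list(
    schema_version = x$schema_version, participant_id = x$participant_id,
    day = x$day, timestamp = x$timestamp, completed = x$completed,
    reason = x$reason,
    zero_cals = lapply(x$zero_cals, enc_zc),
    max_cal = lapply(x$max_cal, enc_mc),
    tasks = lapply(x$tasks, enc_task),
    games = x$games, duration_s = x$duration_s, seed = x$seed
  )
}

req_field <- function(l, field, where) {
  if (!field %in% names(l)) {
    stop(sprintf("malformed session log: missing field '%s' in %s",
                 field, where))
  }
  l[[field]]
}

list_to_record <- function(l) {
  dec_zc <- function(z) structure(
    list(channel = req_field(z, "channel", "zero_cal"), offset = z$offset,
         window_duration = z$window_duration, timestamp = z$timestamp),
    class = "zero_calibration")
  num_or_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  dec_mc <- function(m) structure(
    list(channel = req_field(m, "channel", "max_cal"),
         attempts = as.numeric(unlist(m$attempts)), mean = num_or_na(m$mean),
         rel_dev = num_or_na(m$rel_dev), accepted = m$accepted,
         rounds_used = as.integer(m$rounds_used),
         attempt_history = lapply(m$attempt_history, as.numeric)),
    class = "max_calibration")
  dec_task <- function(tk) {
    cy <- req_field(tk, "cycles", "task")
    structure(
      list(task_kind = req_field(tk, "task_kind", "task"),
           score_pct = req_field(tk, "score_pct", "task"),
           cycles = data.frame(
             cycle = as.integer(unlist(cy$cycle)),
             in_band_fraction = as.numeric(unlist(cy$in_band_fraction)),
             rest_mean_kPa = as.numeric(unlist(cy$rest_mean_kPa))
           ),
           Pmax_used = req_field(tk, "Pmax_used", "task")),
      class = "task_result")
  }
  structure(
    list(schema_version = as.integer(req_field(l, "schema_version", "record")),
         participant_id = req_field(l, "participant_id", "record"),
         day = as.integer(req_field(l, "day", "record")),
         timestamp = l$timestamp,
         completed = req_field(l, "completed", "record"),
         reason = if (is.null(l$reason)) NA_character_ else l$reason,
         zero_cals = lapply(l$zero_cals, dec_zc),
         max_cal = lapply(l$max_cal, dec_mc),
         tasks = lapply(l$tasks, dec_task),
         games = l$games, duration_s = l$duration_s,
         seed = as.integer(l$seed)),
    class = "session_record"
  )
}

#' Write / read the session log archive
#'
#' Logs are archived as schema-versioned JSON (one document per
#' participant or per session) and round-trip exactly:
#' `read_session_log(write_session_log(x, path))` reproduces `x`
#' field for field.
#'
#' @param x a `session_record` or `participant_log`.
#' @param path file path (conventionally `.json`).
#' @return `read_session_log()`: the reconstructed object; a malformed
#'   file raises a parse error naming the offending field.
#' @export
write_session_log <- function(x, path) {
  doc <- if (inherits(x, "participant_log")) {
    list(log_type = "participant",
         participant_id = x$participant_id,
         prescribed_days = as.integer(x$prescribed_days),
         n_prescribed = x$n_prescribed,
         sessions = lapply(x$sessions, record_to_list),
         covariates = x$covariates)
  } else if (inherits(x, "session_record")) {
    c(list(log_type = "session"), record_to_list(x))
  } else {
    stop("x must be a session_record or participant_log")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed session log: ", conditionMessage(e))
  )
  type <- req_field(doc, "log_type", "log")
  if (type == "session") {
    list_to_record(doc)
  } else if (type == "participant") {
    cov <- doc$covariates
    if (!is.null(cov)) cov <- lapply(cov, function(v) v)
    structure(
      list(participant_id = req_field(doc, "participant_id", "log"),
           prescribed_days = as.integer(unlist(doc$prescribed_days)),
           n_prescribed = as.integer(req_field(doc, "n_prescribed", "log")),
           sessions = lapply(doc$sessions, list_to_record),
           covariates = cov),
      class = "participant_log"
    )
  } else {
    stop("malformed session log: unknown log_type '", type, "'")
  }
}
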