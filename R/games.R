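#' Game rules
#'
#' Configuration for the four pressure-driven training games. Each game is
#' a deterministic fixed-timestep state machine on a 1 x 1 unit field,
#' driven by the lip/tongue pressures expressed as fractions of Pmax.
#' The games are motivational filler between metered exercises; their
#' scores are logged but excluded from success-rate analytics.
#'
#' Mechanics (fixed by the device): paddle — ball bounces off top/bottom
#' walls and side paddles moved in proportion to lip (left) and tongue
#' (right) pressure; each paddle bounce increments the counter and speeds
#' the ball up; a miss resets the counter. circle — lip pressure steers
#' horizontally, tongue vertically; holding the point inside the circle
#' for 3 s scores, then the circle shrinks and relocates; a 30 s countdown
#' resets the score on expiry and gains 7 s per success. missile — a
#' tongue press-then-release fires a coloured missile at a 6-sector
#' colour wheel rotated by lip pressure; a colour match scores and speeds
#' the missile up. wall — lip (up) / tongue (down) press-releases move a
#' hole in a wall to let a ball through; each success respawns the ball at
#' a new height with greater speed.
#'
#' Numeric constants (speeds, sizes, increments) are device configuration,
#' not published values.
#'
#' @param variant `"paddle"`, `"circle"`, `"missile"` or `"wall"`.
#' @param fs step rate in Hz; the timestep is `1/fs` (default 50).
#' @param ref_frac pressure fraction of Pmax that maps to full-field
#'   deflection (default 0.10); positions are `clamp(p / ref_frac, 0, 1)`.
#' @param growth speed multiplier per success (default 1.05).
#' @param speed0 initial ball/missile speed in field units per second.
#' @param max_speed speed cap keeping one step's travel well below the
#'   field size.
#' @param paddle_len paddle length (default 0.2).
#' @param circle_r0,circle_shrink,circle_r_floor initial circle radius,
#'   per-success shrink factor and radius floor (0.15, 0.9, 0.05).
#' @param dwell_s seconds the point must stay inside the circle (3).
#' @param timer0_s,timer_bonus_s circle-game countdown start and
#'   per-success bonus (30, 7).
#' @param press_hi,press_lo press-release detector thresholds (fractions
#'   of Pmax): a press arms above `press_hi` (2%), the release fires below
#'   `press_lo` (1%).
#' @param hole_step,hole_half wall-game hole increment (0.1) and half
#'   height (0.05).
#' @return An object of class `game_rules`.
#' @export
game_rules <- function(variant = c("paddle", "circle", "missile", "wall"),
                       fs = 50, ref_frac = 0.10, growth = 1.05,
                       speed0 = 0.6, max_speed = 5,
                       paddle_len = 0.2,
                       circle_r0 = 0.15, circle_shrink = 0.9,
                       circle_r_floor = 0.05,
                       dwell_s = 3, timer0_s = 30, timer_bonus_s = 7,
                       press_hi = 0.02, press_lo = 0.01,
                       hole_step = 0.1, hole_half = 0.05) {
  variant <- match.arg(variant)
  stopifnot(fs > 0, speed0 > 0, growth >= 1, ref_frac > 0,
            press_lo < press_hi)
  structure(
    list(variant = variant, fs = fs, dt = 1 / fs, ref_frac = ref_frac,
         growth = growth, speed0 = speed0, max_speed = max_speed,
         paddle_len = paddle_len, circle_r0 = circle_r0,
         circle_shrink = circle_shrink, circle_r_floor = circle_r_floor,
         dwell_s = dwell_s, timer0_s = timer0_s,
         timer_bonus_s = timer_bonus_s, press_hi = press_hi,
         press_lo = press_lo, hole_step = hole_step, hole_half = hole_half),
    class = "game_rules"
  )
}

#' Game input
#'
#' One timestep of normalized control input: lip and tongue pressures as
#' non-negative fractions of the session's Pmax.
#'
#' @param p_lip,p_tongue pressures as fractions of Pmax (>= 0).
#' @return An object of class `game_input`.
#' @export
game_input <- function(p_lip = 0, p_tongue = 0) {
  if (p_lip < 0 || p_tongue < 0) stop("pressures must be non-negative")
  structure(list(p_lip = p_lip, p_tongue = p_tongue), class = "game_input")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# pressure (fraction of Pmax) -> field position in [0, 1]
press_to_pos <- function(p, rules) clamp(p / rules$ref_frac, 0, 1)

# random direction away from vertical, for ball spawns
spawn_velocity <- function(speed) {
  ang <- stats::runif(1, pi / 8, 3 * pi / 8) +
    sample(c(0, pi / 2, pi, 3 * pi / 2), 1)
  c(vx = speed * cos(ang), vy = speed * sin(ang))
}

# press-then-release edge detector; returns list(armed, fired)
press_release <- function(armed, p, rules) {
  fired <- FALSE
  if (!armed && p >= rules$press_hi) {
    armed <- TRUE
  } else if (armed && p <= rules$press_lo) {
    armed <- FALSE
    fired <- TRUE
  }
  list(armed = armed, fired = fired)
}

#' Initial game state
#'
#' Seeded placements (ball direction, circle position, wall heights) draw
#' from R's RNG stream; [run_game()] seeds it so whole runs replay
#' bit-identically.
#'
#' @param rules a [game_rules()].
#' @return An object of class `game_state`.
#' @export
game_init <- function(rules) {
  s <- list(variant = rules$variant, t = 0, score = 0L, high = 0L)
  s <- switch(rules$variant,
    paddle = c(s, list(
      ball = c(x = 0.5, y = 0.5), vel = spawn_velocity(rules$speed0),
      paddle_lip = 0, paddle_tongue = 0
    )),
    circle = c(s, list(
      point = c(x = 0, y = 0),
      center = circle_spawn(rules$circle_r0),
      radius = rules$circle_r0, dwell = 0, countdown = rules$timer0_s
    )),
    missile = c(s, list(
      wheel_angle = 0, armed = FALSE,
      missile_active = FALSE, missile_y = 0, missile_color = 0L,
      missile_speed = rules$speed0
    )),
    wall = c(s, list(
      ball = c(x = 0, y = stats::runif(1)), speed = rules$speed0,
      hole_y = 0.5, lip_armed = FALSE, tongue_armed = FALSE
    ))
  )
  structure(s, class = "game_state")
}

circle_spawn <- function(radius) {
  c(x = stats::runif(1, radius, 1 - radius),
    y = stats::runif(1, radius, 1 - radius))
}

#' Advance a game by one timestep
#'
#' Pure except for R's RNG, which supplies seeded respawn positions;
#' [run_game()] fixes the seed so trajectories replay exactly.
#'
#' @param state a [game_init()] state matching `rules$variant`.
#' @param input a [game_input()].
#' @param rules a [game_rules()].
#' @return the advanced `game_state`.
#' @export
step_game <- function(state, input, rules) {
  if (!identical(state$variant, rules$variant)) {
    stop("game state does not match rules variant")
  }
  state <- switch(rules$variant,
    paddle = step_paddle(state, input, rules),
    circle = step_circle(state, input, rules),
    missile = step_missile(state, input, rules),
    wall = step_wall(state, input, rules)
  )
  state$t <- state$t + rules$dt
  state$high <- max(state$high, state$score)
  state
}

step_paddle <- function(s, input, rules) {
  top <- 1 - rules$paddle_len
  s$paddle_lip <- clamp(input$p_lip / rules$ref_frac, 0, top)
  s$paddle_tongue <- clamp(input$p_tongue / rules$ref_frac, 0, top)

  s$ball <- s$ball + s$vel * rules$dt
  # top/bottom walls
  if (s$ball["y"] < 0) { s$ball["y"] <- -s$ball["y"]; s$vel["vy"] <- -s$vel["vy"] }
  if (s$ball["y"] > 1) { s$ball["y"] <- 2 - s$ball["y"]; s$vel["vy"] <- -s$vel["vy"] }
  # side paddles: lip guards x = 0, tongue guards x = 1
  bounce_or_miss <- function(s, paddle_y) {
    if (s$ball["y"] >= paddle_y && s$ball["y"] <= paddle_y + rules$paddle_len) {
      s$vel["vx"] <- -s$vel["vx"]
      s$score <- s$score + 1L
      speed <- min(sqrt(sum(s$vel^2)) * rules$growth, rules$max_speed)
      s$vel <- s$vel * speed / sqrt(sum(s$vel^2))
    } else {
      s$score <- 0L
      s$ball <- c(x = 0.5, y = 0.5)
      s$vel <- spawn_velocity(rules$speed0)
      return(s)
    }
    s
  }
  if (s$ball["x"] < 0) {
    s$ball["x"] <- -s$ball["x"]
    s <- bounce_or_miss(s, s$paddle_lip)
  } else if (s$ball["x"] > 1) {
    s$ball["x"] <- 2 - s$ball["x"]
    s <- bounce_or_miss(s, s$paddle_tongue)
  }
  s
}

step_circle <- function(s, input, rules) {
  s$point <- c(x = press_to_pos(input$p_lip, rules),
               y = press_to_pos(input$p_tongue, rules))
  inside <- sqrt(sum((s$point - s$center)^2)) <= s$radius
  s$dwell <- if (inside) s$dwell + rules$dt else 0
  s$countdown <- s$countdown - rules$dt
  if (s$dwell >= rules$dwell_s - 1e-9) {
    s$score <- s$score + 1L
    s$radius <- max(rules$circle_r_floor, s$radius * rules$circle_shrink)
    s$center <- circle_spawn(s$radius)
    s$countdown <- s$countdown + rules$timer_bonus_s
    s$dwell <- 0
  } else if (s$countdown <= 0) {
    s$score <- 0L
    s$countdown <- rules$timer0_s
  }
  s
}

step_missile <- function(s, input, rules) {
  s$wheel_angle <- press_to_pos(input$p_lip, rules) * 2 * pi
  pr <- press_release(s$armed, input$p_tongue, rules)
  s$armed <- pr$armed
  if (pr$fired && !s$missile_active) {
    s$missile_active <- TRUE
    s$missile_y <- 0
    s$missile_color <- sample.int(6L, 1L)
  }
  if (s$missile_active) {
    s$missile_y <- s$missile_y + s$missile_speed * rules$dt
    if (s$missile_y >= 1) {
      sector <- (floor(s$wheel_angle / (2 * pi / 6)) %% 6) + 1L
      if (sector == s$missile_color) {
        s$score <- s$score + 1L
        s$missile_speed <- min(s$missile_speed * rules$growth,
                               rules$max_speed)
      } else {
        s$score <- 0L
      }
      s$missile_active <- FALSE
    }
  }
  s
}

step_wall <- function(s, input, rules) {
  lip <- press_release(s$lip_armed, input$p_lip, rules)
  s$lip_armed <- lip$armed
  if (lip$fired) s$hole_y <- min(1, s$hole_y + rules$hole_step)
  tng <- press_release(s$tongue_armed, input$p_tongue, rules)
  s$tongue_armed <- tng$armed
  if (tng$fired) s$hole_y <- max(0, s$hole_y - rules$hole_step)

  s$ball["x"] <- s$ball["x"] + s$speed * rules$dt
  if (s$ball["x"] >= 1) {
    if (abs(s$ball["y"] - s$hole_y) <= rules$hole_half) {
      s$score <- s$score + 1L
      s$speed <- min(s$speed * rules$growth, rules$max_speed)
    } else {
      s$score <- 0L
    }
    s$ball <- c(x = 0, y = stats::runif(1))
  }
  s
}

#' Run a game for a fixed duration
#'
#' Executes exactly `round(duration_s * rules$fs)` timesteps under a fixed
#' RNG seed, polling `controller` for the input at each step. Given the
#' same `(rules, controller, seed)` the whole trajectory — including every
#' seeded respawn — is bit-identical.
#'
#' @param rules a [game_rules()].
#' @param controller `function(t, state)` returning a [game_input()] (a
#'   plain `list(p_lip=, p_tongue=)` also works).
#' @param duration_s run length in seconds (default 120, the warm-up game
#'   length).
#' @param seed integer RNG seed.
#' @param keep_log if `TRUE`, keep the per-step score log for replay
#'   checks.
#' @return An object of class `game_result`: `variant`, `final_score`,
#'   `high_score`, `steps`, `duration_s`, `seed`, `final_state`, and
#'   (optionally) `log` (data.frame `step`, `t`, `score`, `high`).
#' @export
run_game <- function(rules, controller, duration_s = 120, seed = 1L,
                     keep_log = FALSE) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n_steps <- as.integer(round(duration_s * rules$fs))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  state <- game_init(rules)
  log <- if (keep_log) {
    data.frame(step = seq_len(n_steps), t = NA_real_,
               score = NA_integer_, high = NA_integer_)
  }
  for (i in seq_len(n_steps)) {
    inp <- controller((i - 1) * rules$dt, state)
    if (!inherits(inp, "game_input")) inp <- game_input(inp$p_lip, inp$p_tongue)
    state <- step_game(state, inp, rules)
    if (keep_log) {
      log$t[i] <- state$t
      log$score[i] <- state$score
      log$high[i] <- state$high
    }
  }
  structure(
    list(variant = rules$variant, final_score = state$score,
         high_score = state$high, steps = n_steps, duration_s = duration_s,
         seed = seed, final_state = state, log = log),
    class = "game_result"
  )
}

#' @export
print.game_result <- function(x, ...) {
  cat(sprintf("<game_result> %s: score %d (high %d) over %d steps\n",
              x$variant, x$final_score, x$high_score, x$steps))
  invisible(x)
}
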