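zero_controller <- function(t, state) game_input(0, 0)

test_that("runs are deterministic and step counts exact", {
  for (v in c("paddle", "circle", "missile", "wall")) {
    rules <- game_rules(v)
    ctrl <- function(t, state) {
      game_input(p_lip = 0.05 * (1 + sin(t)), p_tongue = 0.05 * (1 + cos(t)))
    }
    a <- run_game(rules, ctrl, duration_s = 20, seed = 123, keep_log = TRUE)
    b <- run_game(rules, ctrl, duration_s = 20, seed = 123, keep_log = TRUE)
    expect_identical(a$log, b$log)
    expect_equal(a$final_state, b$final_state)
    expect_equal(a$steps, 20 * 50)
  }
  expect_equal(run_game(game_rules("paddle"), zero_controller, 120, 1)$steps,
               6000)
})

test_that("high score is a running maximum and bounds the final score", {
  withr::with_seed(8, ctrl_state <- runif(10))
  noisy <- function(t, state) {
    game_input(p_lip = 0.1 * abs(sin(3 * t + 1)),
               p_tongue = 0.1 * abs(cos(5 * t)))
  }
  for (v in c("paddle", "circle", "missile", "wall")) {
    res <- run_game(game_rules(v), noisy, duration_s = 60, seed = 99,
                    keep_log = TRUE)
    expect_gte(res$high_score, res$final_score)
    expect_true(all(diff(res$log$high) >= 0))
    expect_equal(res$high_score, max(res$log$score))
  }
})

test_that("paddle: zero pressure lets the ball pass and keeps the counter at 0", {
  res <- run_game(game_rules("paddle"), zero_controller, duration_s = 60,
                  seed = 4, keep_log = TRUE)
  # a low ball may graze the bottom-pinned paddle, but the ball must
  # eventually pass it and reset the counter to 0
  expect_true(any(diff(res$log$score) < 0) || all(res$log$score == 0))
  expect_lte(res$final_score, res$high_score)
  expect_true(any(res$log$score == 0))
  st <- res$final_state
  expect_equal(st$paddle_lip, 0)
  expect_equal(st$paddle_tongue, 0)
})

test_that("paddle: a perfect interceptor racks up k bounces with speed growth", {
  # capped speed keeps per-step ball travel below the interceptor's margin
  rules <- game_rules("paddle", growth = 1.05, max_speed = 2)
  # controller that tracks the ball height with both paddles (cheating AI)
  tracker <- function(t, state) {
    y <- max(state$ball["y"] - rules$paddle_len / 2, 0)
    game_input(p_lip = y * rules$ref_frac / 1,
               p_tongue = y * rules$ref_frac / 1)
  }
  res <- run_game(rules, tracker, duration_s = 60, seed = 17, keep_log = TRUE)
  k <- res$final_score
  expect_gt(k, 0)
  expect_equal(res$high_score, k)  # no miss ever happened
  expect_equal(min(res$log$score), 0L)
  expect_true(all(diff(res$log$score) %in% c(0L, 1L)))  # only paddle bounces
  # replay oracle: speed must be v0 * growth^k (capped)
  v <- sqrt(sum(res$final_state$vel^2))
  expect_equal(v, min(rules$speed0 * rules$growth^k, rules$max_speed),
               tolerance = 1e-9)
})

test_that("circle: holding the point inside succeeds at exactly 3 s dwell", {
  rules <- game_rules("circle")
  # controller pinning the point to wherever the circle centre is
  pin <- function(t, state) {
    game_input(p_lip = state$center["x"] * rules$ref_frac,
               p_tongue = state$center["y"] * rules$ref_frac)
  }
  res <- run_game(rules, pin, duration_s = 3.02, seed = 31, keep_log = TRUE)
  expect_equal(res$final_score, 1L)
  first_success <- min(which(res$log$score == 1))
  expect_equal(res$log$t[first_success], 3.0)  # 150th step at 50 Hz
  # countdown right after success = (30 - 3 elapsed) + 7 bonus
  expect_equal(res$final_state$countdown, 30 - res$log$t[first_success] + 7,
               tolerance = 0.05)
  # circle shrank by one 10% step
  expect_equal(res$final_state$radius, rules$circle_r0 * rules$circle_shrink)
})

test_that("circle: countdown expiry resets the score", {
  rules <- game_rules("circle")
  res <- run_game(rules, zero_controller, duration_s = 40, seed = 2,
                  keep_log = TRUE)
  expect_equal(res$final_score, 0L)
  expect_equal(res$final_state$countdown, 30 - (40 - 30), tolerance = 0.05)
})

test_that("wall: press-release events move the hole by one increment", {
  rules <- game_rules("wall")
  # one lip press-release in the first second, nothing else
  pulse <- function(t, state) {
    game_input(p_lip = if (t > 0.2 && t < 0.4) 0.05 else 0, p_tongue = 0)
  }
  res <- run_game(rules, pulse, duration_s = 1, seed = 3)
  expect_equal(res$final_state$hole_y, 0.5 + rules$hole_step)

  both <- function(t, state) {
    game_input(p_lip = if (t > 0.2 && t < 0.4) 0.05 else 0,
               p_tongue = if (t > 0.5 && t < 0.7) 0.05 else 0)
  }
  res2 <- run_game(rules, both, duration_s = 1, seed = 3)
  expect_equal(res2$final_state$hole_y, 0.5)  # up once, down once
})

test_that("missile: press-release fires and a colour match is required to score", {
  rules <- game_rules("missile", speed0 = 2)
  fire_once <- function(t, state) {
    game_input(p_lip = 0, p_tongue = if (t > 0.1 && t < 0.3) 0.05 else 0)
  }
  res <- run_game(rules, fire_once, duration_s = 2, seed = 6, keep_log = TRUE)
  st <- res$final_state
  expect_false(st$missile_active)   # missile resolved within the run
  # wheel pinned at angle 0 -> sector 1; score iff the drawn colour was 1
  expect_equal(res$final_score, if (st$missile_speed > rules$speed0) 1L else 0L)
})

test_that("ball positions stay inside the unit field under random play", {
  withr::with_seed(55, phases <- runif(4, 0, 2 * pi))
  wild <- function(t, state) {
    game_input(p_lip = 0.1 * abs(sin(7 * t + phases[1])),
               p_tongue = 0.1 * abs(sin(11 * t + phases[2])))
  }
  for (seed in 1:5) {
    rules <- game_rules("paddle", speed0 = 1.5)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    st <- game_init(rules)
    ok <- TRUE
    for (i in 1:2000) {
      st <- step_game(st, wild((i - 1) / 50, st), rules)
      ok <- ok && st$ball["x"] >= 0 && st$ball["x"] <= 1 &&
        st$ball["y"] >= 0 && st$ball["y"] <= 1
    }
    expect_true(ok)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
})

test_that("mismatched state and rules raise an error", {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(1)
  st <- game_init(game_rules("paddle"))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  expect_error(step_game(st, game_input(0, 0), game_rules("circle")),
               "variant")
})
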