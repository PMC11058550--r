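test_that("thermal offset follows the first-order closed form", {
  m <- thermal_model(b_inf = 0.5, tau = 20)
  expect_equal(thermal_offset(0, m), 0)
  expect_equal(thermal_offset(1e6, m), 0.5)
  expect_equal(thermal_offset(20, m), 0.5 * (1 - exp(-1)))
  expect_error(thermal_offset(-1, m), "non-negative")
  expect_error(thermal_model(tau = 0), "positive")
})

test_that("the learning curve is exponential toward its asymptote", {
  u <- user_model(skill_0 = 0.6, skill_inf = 0.9, kappa = 9)
  expect_equal(user_skill(u, 0), 0.6)
  sk <- sapply(1:60, user_skill, user = u)
  expect_true(all(diff(sk) > 0))
  expect_equal(user_skill(u, 1000), 0.9)
  expect_equal(user_skill(u, 9), 0.9 - 0.3 * exp(-1))
  # per-task skills resolve by name
  expect_equal(user_skill(user_model(), 1e6, "breathing"), 0.965)
})

test_that("degenerate skills give degenerate task scores", {
  cfg <- tracking_task_config(n_cycles = 3)
  ideal <- user_model(skill_0 = 1, skill_inf = 1, latency_s = 0,
                      rise_tau_s = 1e-4, sigma_rest_frac = 0)
  withr::with_seed(2, {
    tr <- generate_user_trace(ideal, cfg, day = 1, Pmax = 40,
                              thermal = thermal_model(b_inf = 0))
  })
  expect_equal(score_tracking_task(tr, cfg, 40)$score_pct, 100)

  never <- user_model(skill_0 = 0, skill_inf = 0, sigma_rest_frac = 0)
  withr::with_seed(2, {
    tr0 <- generate_user_trace(never, cfg, day = 1, Pmax = 40,
                               thermal = thermal_model(b_inf = 0))
  })
  expect_equal(score_tracking_task(tr0, cfg, 40)$score_pct, 0)
})

test_that("a 0.7 in-band probability is recovered as a ~70% mean score", {
  # 200 simulated cycles pooled; binomial Monte-Carlo tolerance +/- 3
  u <- user_model(skill_0 = 0.7, skill_inf = 0.7)
  cfg <- tracking_task_config(n_cycles = 200)
  withr::with_seed(14, {
    tr <- generate_user_trace(u, cfg, day = 1, Pmax = 40, session_t0 = 300)
  })
  # subtract the steady-state baseline, as the session's zero cal does
  tr <- apply_offset(tr, thermal_offset(300, thermal_model()))
  res <- score_tracking_task(tr, cfg, 40)
  expect_lt(abs(res$score_pct - 70), 3)
  # per-cycle fractions behave like Binomial(75, 0.7) draws
  expect_gt(sd(res$cycles$in_band_fraction), 0.01)
})

test_that("breathing skill maps to the above-threshold fraction", {
  u <- user_model(skill_0 = 0.8, skill_inf = 0.8)
  cfg <- breathing_task_config(n_breaths = 40)  # long task for tight CI
  withr::with_seed(15, {
    tr <- generate_user_trace(u, cfg, day = 1, Pmax = 15, session_t0 = 300)
  })
  tr <- apply_offset(tr, thermal_offset(300, thermal_model()))
  expect_lt(abs(score_breathing_task(tr, cfg, 15)$score_pct - 80), 3)
})

test_that("attendance machinery hits its trivial endpoints", {
  cfgs <- cohort_config(weeks = 4, session = session_config(
    rounds = 1, warmup_s = 5, game_s = 5))
  all_in <- simulate_participant(user_model(adherence = 1, dropout_hazard = 0),
                                 cfgs, seed = 1)
  expect_length(all_in$sessions, 24)

  none <- simulate_participant(user_model(adherence = 0, dropout_hazard = 0),
                               cfgs, seed = 1)
  expect_length(none$sessions, 0)
  expect_equal(compute_compliance(list(none))$overall, 0)

  # dropout hazard 1: gone before the first session
  gone <- simulate_participant(user_model(adherence = 1, dropout_hazard = 1 - 1e-12),
                               cfgs, seed = 1)
  expect_lte(length(gone$sessions), 1)
})

test_that("pre-warm-up zero calibration is biased; post-warm-up is not", {
  # the drifting baseline makes the insertion-time zero estimate
  # underestimate the steady-state offset, which is the device's rationale
  # for repeating the calibration after the two-minute warm-up game
  th <- thermal_model(b_inf = 0.3, tau = 20)
  u <- user_model(sigma_rest_frac = 0.0005)
  withr::with_seed(4, {
    early <- generate_zero_trace(u, 5, Pmax = 40, thermal = th, session_t0 = 0)
    late <- generate_zero_trace(u, 5, Pmax = 40, thermal = th,
                                session_t0 = 125)
  })
  err_early <- abs(compute_zero_offset(early)$offset - th$b_inf)
  err_late <- abs(compute_zero_offset(late)$offset - th$b_inf)
  expect_gt(err_early, err_late)
  expect_gt(err_early, 0.05)   # badly off before equilibration
  expect_lt(err_late, 0.005)   # near-exact at steady state
})

test_that("cohort simulation is reproducible and recovers programmed skills", {
  scfg <- session_config(rounds = 1, warmup_s = 5, game_s = 5)
  ccfg <- cohort_config(n = 3, session = scfg, seed = 42,
                        base_user = user_model(adherence = 1,
                                               dropout_hazard = 0))
  a <- simulate_cohort(ccfg)
  b <- simulate_cohort(ccfg)
  expect_equal(a$covariates, b$covariates)
  expect_equal(length(a$logs), 3)
  # every participant attended everything, so analytics compliance is 100%
  expect_equal(compute_compliance(a$logs)$overall, 1)
  # last-day tongue scores exceed first-day on average (learning programmed)
  ss <- summarize_success(a$logs, "tongue")
  expect_gt(ss$last_mean, ss$first_mean)
})

test_that("programmed monotone association forces Spearman -1 downstream", {
  scfg <- session_config(rounds = 1, warmup_s = 5, game_s = 5)
  co <- simulate_cohort(cohort_config(n = 6, session = scfg, seed = 7,
                                      target_spearman = -1))
  impr <- co$covariates$lip_improvement
  d_sup <- co$covariates$ahi_supine_post - co$covariates$ahi_supine_pre
  expect_equal(spearman_rho(impr, d_sup), -1)
})
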