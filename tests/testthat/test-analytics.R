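test_that("compliance arithmetic matches the per-participant session counts", {
  tab <- study_fixture("sessions")
  completed <- rowSums(tab[, c("week1", "week2", "week3", "week4")])
  cs <- compute_compliance(completed)
  expect_equal(cs$per_participant$compliance[1], 1)        # 24/24
  expect_equal(cs$per_participant$compliance[7], 18 / 24)  # 75%
  expect_equal(cs$total_completed, 175)
  expect_equal(cs$total_prescribed, 192)
  expect_equal(round_half_up(100 * cs$overall), 91)
  expect_equal(min(cs$per_participant$compliance), 0.75)
  expect_error(compute_compliance(numeric(0)), "no participant")
  expect_error(compute_compliance(c(25)), "exceed")
})

test_that("success summaries reproduce the clinical group means", {
  tab <- study_fixture("success")
  tongue <- success_summary(tab$tongue_baseline, tab$tongue_post,
                            task_kind = "tongue")
  expect_equal(tongue$first_mean, 65.875)
  expect_equal(round_half_up(tongue$first_mean), 66)
  expect_equal(round_half_up(tongue$last_mean), 85)
  lip <- success_summary(tab$lip_baseline, tab$lip_post, task_kind = "lip")
  expect_equal(lip$last_mean, 86.75)
  expect_equal(round_half_up(lip$first_mean), 78)
  expect_equal(round_half_up(lip$last_mean), 87)
  # 96% band is mean +/- 1.96 SD, flagged as a dispersion band
  expect_equal(tongue$ci96_first,
               65.875 + c(-1.96, 1.96) * sd(tab$tongue_baseline))
  expect_true(tongue$ci_is_dispersion_band)

  same <- success_summary(rep(70, 5), rep(70, 5))
  expect_equal(same$first_sd, 0)
  expect_equal(same$ci96_first, c(70, 70))
})

test_that("first/last-day extraction uses completed sessions only", {
  mk_task <- function(kind, score) structure(
    list(task_kind = kind, score_pct = score,
         cycles = data.frame(), Pmax_used = 10), class = "task_result")
  mk_sess <- function(day, completed, tongue) structure(
    list(participant_id = "X", day = day, completed = completed,
         tasks = list(mk_task("tongue", tongue), mk_task("lip", 50))),
    class = "session_record")
  log <- structure(
    list(participant_id = "X", prescribed_days = 1:24, n_prescribed = 24,
         sessions = list(mk_sess(1, FALSE, 10), mk_sess(2, TRUE, 40),
                         mk_sess(3, TRUE, 80), mk_sess(4, FALSE, 99)),
         covariates = NULL),
    class = "participant_log")
  ss <- summarize_success(list(log), "tongue")
  expect_equal(ss$per_participant$first, 40)  # day-1 incomplete is skipped
  expect_equal(ss$per_participant$last, 80)
  expect_error(summarize_success(list(log), "breathing"), "absent")
})

test_that("Spearman handles monotone data, ties and degenerate input", {
  x <- c(2, 9, 1, 5, 7)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # tied pair: midranks computed by an independent counting oracle
  xt <- c(1, 2, 3, 4)
  yt <- c(1, 1, 3, 4)
  expect_equal(spearman_rho(xt, yt),
               oracle_pearson(oracle_midrank(xt), oracle_midrank(yt)))
  expect_equal(oracle_midrank(yt), c(1.5, 1.5, 3, 4))
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(19, {
    for (i in 1:15) {
      x <- rnorm(8)
      y <- rnorm(8)
      r <- spearman_rho(x, y)
      expect_equal(spearman_rho(exp(x), y), r)
      expect_equal(spearman_rho(x, qlogis(plogis(y))), r)
      expect_equal(spearman_rho(x^3, 2 * y + 5), r)
    }
  })
})

test_that("exact permutation p-values match full enumeration", {
  # perfectly monotone n = 5: only the identity and the reversal reach |Rs| = 1
  x <- c(3, 1, 4, 2, 5)
  y <- 2 * x + 1
  pt <- permutation_pvalue(x, y)
  expect_true(pt$exact)
  expect_equal(pt$n_perm, 120)
  expect_equal(pt$p_value, 2 / 120)
  expect_gte(pt$p_value, 1 / factorial(pt$n))

  # arbitrary (tied) data against the independent recursive oracle
  xa <- c(1, 2, 3, 4, 5)
  ya <- c(2, 2, 5, 1, 4)
  expect_equal(permutation_pvalue(xa, ya)$p_value, oracle_perm_pvalue(xa, ya))

  # exactness: seed cannot matter at n = 8
  x8 <- c(5, 2, 8, 1, 7, 3, 6, 4)
  y8 <- c(2, 4, 9, 1, 6, 5, 8, 3)
  p1 <- permutation_pvalue(x8, y8, seed = 1)
  p2 <- permutation_pvalue(x8, y8, seed = 999)
  expect_equal(p1$p_value, p2$p_value)
  expect_true(p1$exact)
  expect_equal(p1$n_perm, factorial(8))
})

test_that("Monte-Carlo permutation p-values are roughly uniform under the null", {
  withr::with_seed(23, {
    ps <- replicate(120, {
      x <- rnorm(12)
      y <- rnorm(12)
      permutation_pvalue(x, y, n_mc = 400,
                         seed = sample.int(1e6, 1))$p_value
    })
  })
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
  expect_gt(mean(ps < 0.25), 0.15)
  expect_lt(mean(ps < 0.25), 0.35)
})

test_that("the paired sign-flip test matches its enumeration oracle", {
  expect_equal(paired_permutation_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  pre <- c(10, 12, 9, 14, 11, 13, 8, 15)
  post <- pre + c(2, 1, 3, 2, 1, 2, 4, 1)     # all differences positive
  pt <- paired_permutation_test(pre, post)
  expect_equal(pt$p_value, 2 / 256)
  expect_true(pt$exact)

  pre3 <- c(1.2, 3.4, 2.2)
  post3 <- c(2.0, 3.1, 4.0)
  expect_equal(paired_permutation_test(pre3, post3)$p_value,
               oracle_signflip_pvalue(pre3, post3))
  withr::with_seed(29, {
    for (i in 1:10) {
      a <- rnorm(5)
      b <- rnorm(5)
      expect_equal(paired_permutation_test(a, b)$p_value,
                   oracle_signflip_pvalue(a, b))
    }
  })
})

test_that("the study report aggregates covariates to one decimal", {
  ahi <- study_fixture("ahi")
  covars <- data.frame(participant = ahi$participant,
                       ahi_pre = ahi$ahi_pre, ahi_post = ahi$ahi_post)
  # minimal logs: one completed session each, all three kinds present
  mk_task <- function(kind, score) structure(
    list(task_kind = kind, score_pct = score, cycles = data.frame(),
         Pmax_used = 10), class = "task_result")
  logs <- lapply(seq_len(nrow(ahi)), function(i) {
    sess <- structure(list(participant_id = as.character(i), day = 1,
                           completed = TRUE,
                           tasks = list(mk_task("tongue", 50),
                                        mk_task("lip", 60),
                                        mk_task("breathing", 70))),
                      class = "session_record")
    structure(list(participant_id = as.character(i), prescribed_days = 1:24,
                   n_prescribed = 24, sessions = list(sess),
                   covariates = NULL), class = "participant_log")
  })
  rep <- build_report(logs, covars)
  cm <- rep$covariate_means
  expect_equal(cm$pre[cm$variable == "ahi"], 20.7)
  expect_equal(cm$post[cm$variable == "ahi"], 17.7)
  expect_true(is.na(cm$pre[cm$variable == "ess"]))
  expect_null(rep$lip_supine_spearman)   # no supine columns supplied

  bare <- build_report(logs, NULL)
  expect_null(bare$covariate_means)
  expect_equal(bare$compliance$per_participant$completed, rep_len(1, 8))
})

test_that("pooled compliance equals the participant mean at equal denominators", {
  withr::with_seed(37, {
    for (i in 1:10) {
      counts <- sample(0:24, 8, replace = TRUE)
      cs <- compute_compliance(counts)
      expect_equal(cs$overall, mean(cs$per_participant$compliance))
    }
  })
})
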