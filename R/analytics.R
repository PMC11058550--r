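#' Round half away from zero
#'
#' Report-formatting convention used throughout the analytics: success and
#' compliance percentages round half-up to whole percent, AHI to one
#' decimal (base R's `round()` rounds half to even, which disagrees with
#' the clinical tables at exact halves).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

completed_count <- function(log) {
  if (inherits(log, "participant_log")) {
    sum(vapply(log$sessions, function(s) isTRUE(s$completed), logical(1)))
  } else {
    stop("expected a participant_log")
  }
}

#' Treatment compliance
#'
#' Compliance is the number of completed training sessions divided by the
#' number prescribed (24: six sessions a week for four weeks). A session
#' counts as completed only if every planned task produced a score.
#'
#' @param logs either a list of `participant_log` objects or a numeric
#'   vector of per-participant completed-session counts.
#' @param prescribed prescribed sessions per participant (default 24).
#' @return An object of class `compliance_summary`: `per_participant`
#'   (data.frame with `participant`, `completed`, `compliance`),
#'   `overall` (pooled completed / prescribed), `total_completed`,
#'   `total_prescribed`.
#' @examples
#' compute_compliance(c(24, 20, 24, 22, 22, 23, 18, 22))
#' @export
compute_compliance <- function(logs, prescribed = 24) {
  if (length(logs) == 0L) stop("no participant logs supplied")
  if (is.numeric(logs)) {
    completed <- logs
    ids <- sprintf("P%02d", seq_along(logs))
  } else {
    completed <- vapply(logs, completed_count, numeric(1))
    ids <- vapply(logs, `[[`, character(1), "participant_id")
    prescribed_i <- vapply(logs, function(l) l$n_prescribed, numeric(1))
    if (all(prescribed_i > 0)) prescribed <- prescribed_i
  }
  prescribed <- rep_len(prescribed, length(completed))
  if (any(completed > prescribed)) {
    stop("completed sessions exceed prescribed sessions")
  }
  structure(
    list(per_participant = data.frame(
           participant = ids, completed = completed,
           prescribed = prescribed,
           compliance = completed / prescribed),
         overall = sum(completed) / sum(prescribed),
         total_completed = sum(completed),
         total_prescribed = sum(prescribed)),
    class = "compliance_summary"
  )
}

#' @export
print.compliance_summary <- function(x, ...) {
  cat(sprintf("<compliance_summary> overall %d%% (%d/%d), range %d%%-%d%%\n",
              round_half_up(100 * x$overall), x$total_completed,
              x$total_prescribed,
              round_half_up(100 * min(x$per_participant$compliance)),
              round_half_up(100 * max(x$per_participant$compliance))))
  invisible(x)
}

# mean score of a task kind in the first and last completed session
participant_first_last <- function(log, task_kind) {
  done <- Filter(function(s) isTRUE(s$completed), log$sessions)
  if (length(done) == 0L) stop("participant has no completed session")
  kind_mean <- function(s) {
    sc <- vapply(s$tasks, function(tk) {
      if (tk$task_kind == task_kind) tk$score_pct else NA_real_
    }, numeric(1))
    sc <- sc[!is.na(sc)]
    if (length(sc) == 0L) stop("task kind '", task_kind,
                               "' absent from session")
    mean(sc)
  }
  list(first = kind_mean(done[[1L]]),
       last = kind_mean(done[[length(done)]]))
}

#' First-day / last-day success summary
#'
#' For each participant, averages the scores of all tasks of one kind in
#' their first and last completed sessions, then summarises across
#' participants with mean, SD and the 96% interval reported as
#' `mean +/- 1.96 SD`. That interval is a dispersion band over raw values
#' (the reporting convention of the clinical evaluation), not a standard
#' error based confidence interval; the summary carries a
#' `ci_is_dispersion_band` flag to make this explicit.
#'
#' @param logs list of `participant_log` objects.
#' @param task_kind `"tongue"`, `"lip"` or `"breathing"`.
#' @return An object of class `success_summary`: `per_participant`
#'   (data.frame `participant`, `first`, `last`), `first_mean`,
#'   `first_sd`, `last_mean`, `last_sd`, `ci96_first`, `ci96_last`,
#'   `task_kind`, `ci_is_dispersion_band = TRUE`.
#' @export
summarize_success <- function(logs, task_kind = c("tongue", "lip",
                                                  "breathing")) {
  task_kind <- match.arg(task_kind)
  if (length(logs) == 0L) stop("no participant logs supplied")
  fl <- lapply(logs, participant_first_last, task_kind = task_kind)
  first <- vapply(fl, `[[`, numeric(1), "first")
  last <- vapply(fl, `[[`, numeric(1), "last")
  ids <- vapply(logs, `[[`, character(1), "participant_id")
  success_summary(first, last, ids, task_kind)
}

#' Success summary from paired first/last scores
#'
#' The same across-participant summary as [summarize_success()], applied
#' directly to per-participant baseline and post-training scores (for
#' example the bundled clinical success-rate fixture).
#'
#' @param first,last numeric vectors of per-participant scores (percent).
#' @param ids participant identifiers.
#' @param task_kind label.
#' @return a `success_summary`.
#' @export
success_summary <- function(first, last, ids = sprintf("P%02d",
                                                       seq_along(first)),
                            task_kind = "tongue") {
  if (length(first) != length(last)) stop("first/last lengths differ")
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  structure(
    list(per_participant = data.frame(participant = ids, first = first,
                                      last = last),
         first_mean = mean(first), first_sd = sd0(first),
         last_mean = mean(last), last_sd = sd0(last),
         ci96_first = mean(first) + c(-1, 1) * 1.96 * sd0(first),
         ci96_last = mean(last) + c(-1, 1) * 1.96 * sd0(last),
         task_kind = task_kind, ci_is_dispersion_band = TRUE),
    class = "success_summary"
  )
}

#' @export
print.success_summary <- function(x, ...) {
  cat(sprintf(
    "<success_summary> %s: first day %d%% (SD %.0f), last day %d%% (SD %.0f)\n",
    x$task_kind, round_half_up(x$first_mean), x$first_sd,
    round_half_up(x$last_mean), x$last_sd))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Midrank (average-rank) handling of ties: the coefficient is the Pearson
#' correlation of the two rank vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Rs in \[-1, 1\]. A constant vector raises an "undefined
#'   correlation" error.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

# all permutations of 1..n as an (n! x n) integer matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    blk <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Permutation p-value for a correlation
#'
#' Two-sided permutation test of association: `y` is permuted against `x`
#' and the proportion of permutations with `|statistic| >= |observed|`
#' (the identity permutation included) is returned. With `n <= n_exact`
#' (default 8, 8! = 40320 permutations) the enumeration is exhaustive and
#' the p-value exact and seed-independent; larger samples use seeded
#' Monte-Carlo sampling of at least `n_mc` permutations with the +1
#' identity correction.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param statistic association statistic (default [spearman_rho()], for
#'   which the enumeration is computed in closed form over rank vectors).
#' @param n_exact largest n for exhaustive enumeration.
#' @param n_mc Monte-Carlo permutations when not exhaustive.
#' @param seed RNG seed (Monte-Carlo mode only).
#' @return An object of class `perm_test`: `p_value`, `statistic`
#'   (observed), `n`, `exact`, `n_perm`.
#' @export
permutation_pvalue <- function(x, y, statistic = spearman_rho,
                               n_exact = 8L, n_mc = 10000L, seed = 1L) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  obs <- statistic(x, y)
  tol <- 1e-12
  if (n <= n_exact) {
    P <- all_perms(n)
    if (identical(statistic, spearman_rho)) {
      rx <- rank(x)
      ry <- rank(y)
      if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
        stop("undefined correlation: constant vector")
      }
      cross <- matrix(ry[P], nrow(P), n) %*% rx
      stats_all <- (cross - n * mean(rx) * mean(ry)) /
        ((n - 1) * stats::sd(rx) * stats::sd(ry))
    } else {
      stats_all <- apply(P, 1L, function(idx) statistic(x, y[idx]))
    }
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    n_perm <- nrow(P)
    exact <- TRUE
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    stats_all <- replicate(n_mc, statistic(x, y[sample.int(n)]))
    p <- (1 + sum(abs(stats_all) >= abs(obs) - tol)) / (n_mc + 1)
    n_perm <- n_mc
    exact <- FALSE
  }
  structure(list(p_value = p, statistic = obs, n = n, exact = exact,
                 n_perm = n_perm),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> stat=%.3f, p=%.4g (%s, %d permutations, n=%d)\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "Monte-Carlo", x$n_perm, x$n))
  invisible(x)
}

#' Paired sign-flip permutation test
#'
#' Two-sided test of a pre/post difference in paired data: the statistic
#' is the mean difference and the reference distribution flips the sign
#' of each pair's difference. Exhaustive over all `2^n` sign patterns for
#' `n <= n_exact` (default 20), seeded Monte-Carlo otherwise. This is the
#' package's inference for pre/post comparisons; it is a substitute for,
#' not a replication of, random-intercept mixed-model inference.
#'
#' @param pre,post paired numeric vectors, length >= 2.
#' @param n_exact largest n for exhaustive enumeration.
#' @param n_mc Monte-Carlo sign patterns otherwise.
#' @param seed RNG seed (Monte-Carlo mode only).
#' @return a `perm_test` (statistic = mean of `post - pre`).
#' @export
paired_permutation_test <- function(pre, post, n_exact = 20L,
                                    n_mc = 20000L, seed = 1L) {
  n <- length(pre)
  if (n != length(post)) stop("pre and post must have equal length")
  if (n < 2L) stop("need at least 2 pairs")
  d <- post - pre
  obs <- mean(d)
  tol <- 1e-12
  if (n <= n_exact) {
    sums <- 0
    for (di in d) sums <- c(sums, sums + di)  # all subset sums of d
    stats_all <- (sum(d) - 2 * sums) / n      # mean under each sign pattern
    p <- mean(abs(stats_all) >= abs(obs) - tol)
    exact <- TRUE
    n_perm <- 2^n
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    stats_all <- replicate(n_mc, mean(d * sample(c(-1, 1), n, replace = TRUE)))
    p <- (1 + sum(abs(stats_all) >= abs(obs) - tol)) / (n_mc + 1)
    exact <- FALSE
    n_perm <- n_mc
  }
  structure(list(p_value = p, statistic = obs, n = n, exact = exact,
                 n_perm = n_perm),
            class = "perm_test")
}

#' Assemble the study report
#'
#' Combines compliance, first-day/last-day success trajectories for all
#' three task kinds, pre/post covariate means (1 decimal), and the
#' Spearman association between lip-task improvement and the change in
#' supine AHI with its exact permutation p-value. Missing covariates are
#' reported as absent rather than raising an error.
#'
#' @param logs list of `participant_log` objects.
#' @param covariates optional data.frame with columns `participant` and
#'   any of `ahi_pre`, `ahi_post`, `ahi_supine_pre`, `ahi_supine_post`,
#'   `ess_pre`, `ess_post`.
#' @return An object of class `study_report`: `compliance`, `success`
#'   (named list by task kind), `covariate_means` (data.frame `variable`,
#'   `pre`, `post`), `lip_supine_spearman` (a `perm_test` or `NULL`).
#' @export
build_report <- function(logs, covariates = NULL) {
  if (length(logs) == 0L) stop("no participant logs supplied")
  compliance <- compute_compliance(logs)
  success <- lapply(
    stats::setNames(nm = c("tongue", "lip", "breathing")),
    function(kind) tryCatch(summarize_success(logs, kind),
                            error = function(e) NULL)
  )
  covariate_means <- NULL
  lip_sp <- NULL
  if (!is.null(covariates) && nrow(covariates) > 0L) {
    vars <- c("ahi", "ahi_supine", "ess")
    covariate_means <- do.call(rbind, lapply(vars, function(v) {
      pre_col <- paste0(v, "_pre")
      post_col <- paste0(v, "_post")
      data.frame(
        variable = v,
        pre = if (pre_col %in% names(covariates)) {
          round_half_up(mean(covariates[[pre_col]]), 1)
        } else NA_real_,
        post = if (post_col %in% names(covariates)) {
          round_half_up(mean(covariates[[post_col]]), 1)
        } else NA_real_
      )
    }))
    has_supine <- all(c("ahi_supine_pre", "ahi_supine_post") %in%
                        names(covariates))
    if (has_supine && !is.null(success$lip) &&
        nrow(covariates) == nrow(success$lip$per_participant)) {
      impr <- success$lip$per_participant$last -
        success$lip$per_participant$first
      d_supine <- covariates$ahi_supine_post - covariates$ahi_supine_pre
      lip_sp <- tryCatch(permutation_pvalue(impr, d_supine),
                         error = function(e) NULL)
    }
  }
  structure(
    list(compliance = compliance, success = success,
         covariate_means = covariate_means, lip_supine_spearman = lip_sp),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  print(x$compliance)
  for (s in x$success) if (!is.null(s)) print(s)
  if (!is.null(x$covariate_means)) {
    cat("covariate means (pre -> post):\n")
    for (i in seq_len(nrow(x$covariate_means))) {
      cat(sprintf("  %-10s %.1f -> %.1f\n", x$covariate_means$variable[i],
                  x$covariate_means$pre[i], x$covariate_means$post[i]))
    }
  }
  if (!is.null(x$lip_supine_spearman)) {
    cat(sprintf("lip improvement vs supine-AHI change: Rs=%.2f, p=%.3g\n",
                x$lip_supine_spearman$statistic,
                x$lip_supine_spearman$p_value))
  }
  invisible(x)
}
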