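#' Thermal baseline model
#'
#' The silicone mouthpiece warms after insertion and the cavity baseline
#' pressure drifts with it, approaching steady state after about a minute.
#' Modelled as a first-order exponential: `b(t) = b_inf * (1 - exp(-t/tau))`
#' with `t` seconds since insertion. This is why the device repeats the
#' zero calibration after the two-minute warm-up game.
#'
#' @param b_inf asymptotic baseline offset in kPa (default 0.15).
#' @param tau time constant in seconds (default 20, putting the baseline
#'   within 5% of steady state at one minute).
#' @return An object of class `thermal_model`.
#' @export
thermal_model <- function(b_inf = 0.15, tau = 20) {
  if (tau <= 0) stop("tau must be positive")
  structure(list(b_inf = b_inf, tau = tau), class = "thermal_model")
}

#' Thermal baseline offset at time t
#'
#' @param t seconds since mouthpiece insertion (>= 0); vectorised.
#' @param model a [thermal_model()].
#' @return offset in kPa.
#' @export
thermal_offset <- function(t, model = thermal_model()) {
  if (any(t < 0)) stop("t must be non-negative")
  model$b_inf * (1 - exp(-t / model$tau))
}

#' Synthetic participant model
#'
#' Describes one simulated participant: true maximal pressures, a learning
#' curve of per-sample in-band probability across training days, motor
#' latency and noise, attempt-to-attempt variability in the maximal
#' pressure calibration, and attendance behaviour.
#'
#' The skill on training day `d` follows
#' `skill(d) = skill_inf - (skill_inf - skill_0) * exp(-d / kappa)`,
#' the saturating exponential learning curve typical of motor training.
#' `skill_0` and `skill_inf` may be single numbers or named vectors with
#' elements `tongue`, `lip`, `breathing`; the defaults reproduce the study
#' conditions of the 4-week evaluation (tongue success rising from about
#' 66% to 85%, lip 78% to 87%, breathing 86% to 96% over 28 days).
#'
#' @param Pmax_true named vector `c(lip=, tongue=)` of true maximal
#'   pressures in kPa. Defaults (lip 15, tongue 40) are typical adult
#'   orofacial pressures.
#' @param skill_0 day-0 in-band probability (scalar or per-task vector).
#' @param skill_inf asymptotic in-band probability.
#' @param kappa learning time constant in days (default 9).
#' @param latency_s reaction latency at target onset in seconds
#'   (default 0.8, inside the 1.5 s unscored reaction window).
#' @param rise_tau_s time constant of the first-order approach to the
#'   target level (default 0.15 s).
#' @param sigma_rest_frac rest-phase pressure noise, fraction of Pmax.
#' @param attempt_cv coefficient of variation of maximal-pressure attempt
#'   peaks (default 0.025; spreads large enough to trigger occasional
#'   7.5%-rule repeats).
#' @param adherence probability of attending a prescribed session
#'   (default 0.91, the study's average compliance).
#' @param dropout_hazard per-day probability of abandoning the program
#'   (default 0.008, a geometric hazard giving roughly a 20% four-week
#'   dropout rate — two in ten).
#' @param id participant identifier.
#' @return An object of class `user_model`.
#' @export
user_model <- function(Pmax_true = c(lip = 15, tongue = 40),
                       skill_0 = c(tongue = 0.635, lip = 0.769,
                                   breathing = 0.847),
                       skill_inf = c(tongue = 0.860, lip = 0.875,
                                     breathing = 0.965),
                       kappa = 9, latency_s = 0.8, rise_tau_s = 0.15,
                       sigma_rest_frac = 0.005, attempt_cv = 0.025,
                       adherence = 0.91, dropout_hazard = 0.008,
                       id = "P01") {
  if (any(skill_0 < 0) || any(skill_inf > 1) ||
      any(pick_skill_pair(skill_0, skill_inf) < 0)) {
    stop("skills must satisfy 0 <= skill_0 <= skill_inf <= 1")
  }
  if (latency_s < 0 || sigma_rest_frac < 0) {
    stop("latency and noise must be non-negative")
  }
  if (!(adherence >= 0 && adherence <= 1)) stop("adherence must be in [0,1]")
  structure(
    list(Pmax_true = Pmax_true, skill_0 = skill_0, skill_inf = skill_inf,
         kappa = kappa, latency_s = latency_s, rise_tau_s = rise_tau_s,
         sigma_rest_frac = sigma_rest_frac, attempt_cv = attempt_cv,
         adherence = adherence, dropout_hazard = dropout_hazard, id = id),
    class = "user_model"
  )
}

# elementwise skill_inf - skill_0 across scalar/named-vector combinations
pick_skill_pair <- function(s0, sinf) {
  kinds <- union(names(s0), names(sinf))
  if (length(kinds) == 0L) return(sinf - s0)
  vapply(kinds, function(k) pick_named(sinf, k) - pick_named(s0, k),
         numeric(1))
}

pick_named <- function(x, kind) {
  if (is.null(names(x))) x[[1]] else if (kind %in% names(x)) x[[kind]] else x[[1]]
}

#' Learning-curve skill on a given day
#'
#' @param user a [user_model()].
#' @param day training day (1-based).
#' @param task_kind `"tongue"`, `"lip"` or `"breathing"`.
#' @return in-band probability in \[0, 1\].
#' @export
user_skill <- function(user, day, task_kind = "tongue") {
  s0 <- pick_named(user$skill_0, task_kind)
  sinf <- pick_named(user$skill_inf, task_kind)
  sinf - (sinf - s0) * exp(-day / user$kappa)
}

# Tracking noise SD from a target in-band probability: with pressure
# Normal(center, s) and band half-width h, P(in band) = 2*pnorm(h/s) - 1,
# so s = h / qnorm((1 + skill) / 2).
noise_sd_for_skill <- function(skill, half_width) {
  if (skill >= 1 - 1e-12) return(0)
  half_width / stats::qnorm((1 + skill) / 2)
}

#' Generate a synthetic task trace for one participant-day
#'
#' Produces the raw (uncorrected) pressure trace a participant would
#' develop during one task, including the thermal baseline drift; the
#' session engine subtracts the zero-calibration offset before scoring.
#'
#' Tracking tasks: during each target phase, after a motor latency the
#' pressure rises first-order to the band centre; Gaussian noise is scaled
#' so that the per-sample in-band probability equals `user_skill(user,
#' day, kind)` (see the noise inversion in the source). During rest the
#' pressure is near zero. Breathing task: the held level is placed at
#' `threshold + qnorm(skill) * s0` with fixed noise `s0 = 1%` of Pmax, so
#' the per-sample above-threshold probability equals the skill. Draws come
#' from R's ambient RNG; seed upstream for determinism.
#'
#' @param user a [user_model()].
#' @param cfg a [tracking_task_config()] or [breathing_task_config()].
#' @param day training day, drives the learning curve.
#' @param Pmax the displayed maximal pressure (kPa) the participant tracks
#'   against (the session's calibrated value).
#' @param thermal a [thermal_model()].
#' @param session_t0 seconds since mouthpiece insertion at task start.
#' @param fs sampling rate in Hz.
#' @return a [pressure_trace()] for `cfg`'s channel, `t0 = 0`.
#' @export
generate_user_trace <- function(user, cfg, day, Pmax,
                                thermal = thermal_model(), session_t0 = 300,
                                fs = 50) {
  dur <- task_duration(cfg)
  n <- as.integer(round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  base <- thermal_offset(session_t0 + t, thermal)
  rest_noise <- stats::rnorm(n, 0, user$sigma_rest_frac * Pmax)

  if (inherits(cfg, "breathing_task_config")) {
    skill <- user_skill(user, day, "breathing")
    if (skill <= 0) return(pressure_trace(base + rest_noise, fs, cfg$channel))
    s0 <- 0.01 * Pmax
    mu <- cfg$threshold_frac * Pmax +
      stats::qnorm(clamp(skill, 1e-9, 1 - 1e-9)) * s0
    p <- base + pmax(mu + stats::rnorm(n, 0, s0), 0)
    return(pressure_trace(p, fs, cfg$channel))
  }

  skill <- user_skill(user, day, cfg$channel)
  center <- (cfg$band$lo + cfg$band$hi) / 2 * Pmax
  half <- (cfg$band$hi - cfg$band$lo) / 2 * Pmax
  s_track <- noise_sd_for_skill(clamp(skill, 1e-9, 1), half)
  p <- base + rest_noise
  if (skill > 0) {
    cycle_s <- cfg$rest_s + cfg$target_s
    for (k in seq_len(cfg$n_cycles) - 1L) {
      onset <- k * cycle_s + cfg$rest_s + user$latency_s
      stop_t <- k * cycle_s + cycle_s
      idx <- which(t >= onset & t < stop_t)
      if (length(idx) == 0L) next
      level <- center * (1 - exp(-(t[idx] - onset) / user$rise_tau_s))
      p[idx] <- base[idx] + level + stats::rnorm(length(idx), 0, s_track)
    }
  }
  pressure_trace(p, fs, cfg$channel)
}

#' Generate a released-pressure (zero-calibration) trace
#'
#' @inheritParams generate_user_trace
#' @param duration_s trace length in seconds.
#' @param channel cavity.
#' @return a [pressure_trace()].
#' @export
generate_zero_trace <- function(user, duration_s, Pmax,
                                thermal = thermal_model(), session_t0 = 0,
                                fs = 50, channel = "tongue") {
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  p <- thermal_offset(session_t0 + t, thermal) +
    stats::rnorm(n, 0, user$sigma_rest_frac * Pmax)
  pressure_trace(p, fs, channel)
}

#' Draw maximal-pressure attempt peaks for one round
#'
#' Peaks are `Pmax_true * exp(attempt_cv * z)` with standard-normal `z`,
#' i.e. lognormal multiplicative attempt-to-attempt variability.
#'
#' @param user a [user_model()].
#' @param channel `"lip"` or `"tongue"`.
#' @param n attempts per round.
#' @return numeric vector of peaks in kPa.
#' @export
generate_attempt_peaks <- function(user, channel, n = 3) {
  user$Pmax_true[[channel]] * exp(user$attempt_cv * stats::rnorm(n))
}

#' Cohort configuration
#'
#' Study-level simulation settings: cohort size, calendar, between-
#' participant variability and the programmed association between lip
#' success improvement and supine-AHI change.
#'
#' @param n participants (default 8, the number of program completers in
#'   the evaluation study).
#' @param weeks training weeks (default 4).
#' @param sessions_per_week prescribed sessions per week (default 6; the
#'   seventh day of each week is a rest day).
#' @param base_user the template [user_model()].
#' @param skill_jitter_sd between-participant SD added to `skill_0` and
#'   `skill_inf` on the logit scale (default 0.55, spreading day-1 task
#'   scores over roughly the 34%-92% range seen across participants).
#' @param pmax_sdlog between-participant lognormal SD of Pmax (0.25).
#' @param target_spearman programmed Spearman correlation between lip
#'   success improvement and the change in supine AHI (default -0.76).
#' @param ahi_pre_meanlog,ahi_pre_sdlog lognormal parameters of the
#'   pretraining AHI (defaults give a median near 18 events/h).
#' @param supine_ratio multiplicative factor from AHI to supine AHI
#'   (default 1.6).
#' @param supine_change_mean,supine_change_sd Normal parameters of the
#'   supine-AHI change, events/h (defaults -6.7 and 8).
#' @param session the [session_config()] used for every simulated session.
#' @param seed base RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 8, weeks = 4, sessions_per_week = 6,
                          base_user = user_model(),
                          skill_jitter_sd = 0.55, pmax_sdlog = 0.25,
                          target_spearman = -0.76,
                          ahi_pre_meanlog = log(18), ahi_pre_sdlog = 0.5,
                          supine_ratio = 1.6,
                          supine_change_mean = -6.7, supine_change_sd = 8,
                          session = session_config(), seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (abs(target_spearman) > 1) stop("target_spearman must be in [-1, 1]")
  structure(
    list(n = n, weeks = weeks, sessions_per_week = sessions_per_week,
         base_user = base_user, skill_jitter_sd = skill_jitter_sd,
         pmax_sdlog = pmax_sdlog, target_spearman = target_spearman,
         ahi_pre_meanlog = ahi_pre_meanlog, ahi_pre_sdlog = ahi_pre_sdlog,
         supine_ratio = supine_ratio,
         supine_change_mean = supine_change_mean,
         supine_change_sd = supine_change_sd,
         session = session, seed = seed),
    class = "cohort_config"
  )
}

#' Prescribed training calendar
#'
#' Day indices (1-based) of prescribed sessions: the first
#' `sessions_per_week` days of each week, the remaining day resting.
#'
#' @param weeks number of weeks.
#' @param sessions_per_week prescribed sessions per week (<= 7).
#' @return integer vector of day indices.
#' @export
prescribed_days <- function(weeks = 4, sessions_per_week = 6) {
  if (sessions_per_week > 7) stop("at most 7 sessions per week")
  unlist(lapply(seq_len(weeks) - 1L, function(w) {
    7L * w + seq_len(sessions_per_week)
  }))
}

#' Simulate one participant's 4-week program
#'
#' Walks the prescribed calendar day by day. The participant drops out
#' with a geometric per-day hazard; until dropout, each prescribed session
#' is attended independently with the model's adherence probability, and
#' every attended session is run in full through [run_session()].
#'
#' @param user a [user_model()].
#' @param cfg a [cohort_config()] (calendar and session settings).
#' @param seed RNG seed for this participant.
#' @return An object of class `participant_log`: fields `participant_id`,
#'   `prescribed_days`, `n_prescribed`, `sessions` (list of session
#'   records), `covariates` (NULL until a cohort attaches them).
#' @export
simulate_participant <- function(user, cfg = cohort_config(), seed = 1L) {
  set.seed(seed)
  days <- prescribed_days(cfg$weeks, cfg$sessions_per_week)
  n_days <- cfg$weeks * 7L
  dropout_day <- if (user$dropout_hazard > 0) {
    1L + stats::rgeom(1, user$dropout_hazard)  # first day no longer training
  } else {
    Inf
  }
  attend <- stats::runif(length(days)) < user$adherence
  sessions <- list()
  for (i in seq_along(days)) {
    day <- days[i]
    if (day > n_days || day >= dropout_day || !attend[i]) next
    rec <- run_session(user, day = day, config = cfg$session,
                       seed = derive_seed(seed, day))
    sessions[[length(sessions) + 1L]] <- rec
  }
  structure(
    list(participant_id = user$id, prescribed_days = days,
         n_prescribed = length(days), sessions = sessions,
         covariates = NULL),
    class = "participant_log"
  )
}

#' @export
print.participant_log <- function(x, ...) {
  done <- sum(vapply(x$sessions, function(s) isTRUE(s$completed), logical(1)))
  cat(sprintf("<participant_log> %s: %d/%d sessions completed\n",
              x$participant_id, done, x$n_prescribed))
  invisible(x)
}

# small deterministic seed mixer, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629)
}

#' Simulate a training cohort
#'
#' Draws `n` participants around the template user model (lognormal Pmax,
#' logit-jittered skills), simulates each full program, then generates
#' synthetic pre/post clinical covariates. The change in supine AHI is
#' coupled to each participant's simulated lip-task improvement through a
#' Gaussian copula whose latent correlation is chosen as
#' `rho = 2 * sin(pi * rs / 6)` so that the programmed Spearman `rs` is
#' exact in expectation; `rs = -1` reduces to exactly reversed ranks.
#'
#' @param cfg a [cohort_config()].
#' @return An object of class `cohort` with fields `logs` (list of
#'   [simulate_participant()] logs, covariates attached), `covariates`
#'   (data.frame), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  set.seed(cfg$seed)
  users <- lapply(seq_len(cfg$n), function(i) {
    u <- cfg$base_user
    u$id <- sprintf("P%02d", i)
    u$Pmax_true <- u$Pmax_true * exp(stats::rnorm(2, 0, cfg$pmax_sdlog))
    jit <- stats::rnorm(1, 0, cfg$skill_jitter_sd)  # shared person effect
    u$skill_0 <- stats::plogis(stats::qlogis(clamp(u$skill_0, 1e-6, 1 - 1e-6)) + jit)
    u$skill_inf <- pmax(stats::plogis(
      stats::qlogis(clamp(u$skill_inf, 1e-6, 1 - 1e-6)) + jit), u$skill_0)
    u
  })
  part_seeds <- sample.int(2147480000L, cfg$n)
  logs <- lapply(seq_len(cfg$n), function(i) {
    simulate_participant(users[[i]], cfg, seed = part_seeds[i])
  })

  set.seed(derive_seed(cfg$seed, 777L))
  covar <- synth_covariates(logs, cfg)
  for (i in seq_along(logs)) {
    logs[[i]]$covariates <- as.list(covar[i, -1, drop = FALSE])
  }
  structure(list(logs = logs, covariates = covar, config = cfg),
            class = "cohort")
}

# pre/post clinical covariates; supine-AHI change copula-coupled to the
# simulated lip improvement
synth_covariates <- function(logs, cfg) {
  n <- length(logs)
  impr <- vapply(logs, function(lg) {
    tr <- tryCatch(participant_first_last(lg, "lip"), error = function(e) NULL)
    if (is.null(tr)) NA_real_ else tr$last - tr$first
  }, numeric(1))
  impr[is.na(impr)] <- stats::rnorm(sum(is.na(impr)), 0, 1e-3)

  rs <- cfg$target_spearman
  u1 <- (rank(impr, ties.method = "average") - 0.5) / n
  if (abs(rs) >= 1 - 1e-12) {
    z2 <- sign(rs) * stats::qnorm(u1)
  } else {
    rho <- 2 * sin(pi * rs / 6)
    z2 <- rho * stats::qnorm(u1) +
      sqrt(1 - rho^2) * stats::rnorm(n)
  }

  ahi_pre <- stats::rlnorm(n, cfg$ahi_pre_meanlog, cfg$ahi_pre_sdlog)
  supine_pre <- ahi_pre * cfg$supine_ratio
  # supine-AHI change: one common strictly monotone quantile transform of
  # the latent copula variable, a Normal truncated below at -min(pre) so
  # every post value stays non-negative without clipping (clipping would
  # break the programmed rank coupling)
  u2 <- stats::pnorm(z2)
  f_lo <- stats::pnorm(-min(supine_pre), cfg$supine_change_mean,
                       cfg$supine_change_sd)
  d_supine <- stats::qnorm(f_lo + u2 * (1 - f_lo),
                           cfg$supine_change_mean, cfg$supine_change_sd)
  supine_post <- supine_pre + d_supine
  ahi_post <- pmax(ahi_pre + d_supine / cfg$supine_ratio +
                     stats::rnorm(n, 0, 2), 0)
  ess_pre <- clamp(round(stats::rnorm(n, 11.3, 5.8)), 0, 24)
  ess_post <- clamp(ess_pre + round(stats::rnorm(n, -1.8, 3)), 0, 24)
  data.frame(
    participant = vapply(logs, `[[`, character(1), "participant_id"),
    ahi_pre = ahi_pre, ahi_post = ahi_post,
    ahi_supine_pre = supine_pre, ahi_supine_post = supine_post,
    ess_pre = ess_pre, ess_post = ess_post,
    lip_improvement = impr
  )
}
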