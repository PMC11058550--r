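# Independent brute-force oracles used to check the package's vectorised
# implementations. Deliberately written as plain per-sample loops and
# explicit sum formulas, sharing no code with the package internals.

oracle_window_mean <- function(trace, start, end) {
  total <- 0
  count <- 0
  for (i in seq_along(trace$values)) {
    ti <- trace$t0 + (i - 1) / trace$fs
    if (ti >= start && ti < end) {
      total <- total + trace$values[i]
      count <- count + 1
    }
  }
  if (count == 0) stop("empty window")
  total / count
}

oracle_fraction_in_band <- function(trace, start, end, lo, hi) {
  n_in <- 0
  count <- 0
  for (i in seq_along(trace$values)) {
    ti <- trace$t0 + (i - 1) / trace$fs
    if (ti >= start && ti < end) {
      count <- count + 1
      p <- trace$values[i]
      if (p >= lo && p <= hi) n_in <- n_in + 1
    }
  }
  n_in / count
}

oracle_fraction_above <- function(trace, start, end, thr) {
  n_in <- 0
  count <- 0
  for (i in seq_along(trace$values)) {
    ti <- trace$t0 + (i - 1) / trace$fs
    if (ti >= start && ti < end) {
      count <- count + 1
      if (trace$values[i] >= thr) n_in <- n_in + 1
    }
  }
  n_in / count
}

# dense-resampling tracking-score oracle: evaluates an analytic pressure
# signal at `mult` times the device rate and loops per sample over the
# scored windows of each cycle
oracle_score_tracking <- function(signal_fn, cfg, Pmax, fs, mult = 10) {
  fsd <- fs * mult
  lo <- cfg$band$lo * Pmax
  hi <- cfg$band$hi * Pmax
  cyc <- cfg$rest_s + cfg$target_s
  fracs <- numeric(cfg$n_cycles)
  for (k in seq_len(cfg$n_cycles)) {
    s <- (k - 1) * cyc + cfg$rest_s + cfg$react_s
    e <- k * cyc
    n_in <- 0
    count <- 0
    t <- s
    while (t < e - 1e-12) {
      p <- signal_fn(t)
      count <- count + 1
      if (p >= lo && p <= hi) n_in <- n_in + 1
      t <- t + 1 / fsd
    }
    fracs[k] <- n_in / count
  }
  100 * mean(fracs)
}

oracle_score_breathing <- function(signal_fn, cfg, Pmax, fs, mult = 10) {
  fsd <- fs * mult
  thr <- cfg$threshold_frac * Pmax
  dur <- cfg$n_breaths * (cfg$inhale_s + cfg$exhale_s)
  n_in <- 0
  count <- 0
  t <- 0
  while (t < dur - 1e-12) {
    count <- count + 1
    if (signal_fn(t) >= thr) n_in <- n_in + 1
    t <- t + 1 / fsd
  }
  100 * n_in / count
}

# explicit-sum Pearson correlation (hand formula)
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# midrank ranks by counting (independent of base rank())
oracle_midrank <- function(v) {
  sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
}

# recursive permutation enumeration for the exact-test oracles
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_perm_pvalue <- function(x, y) {
  obs <- abs(oracle_pearson(oracle_midrank(x), oracle_midrank(y)))
  hits <- 0
  perms <- oracle_perms(seq_along(y))
  for (p in perms) {
    s <- abs(oracle_pearson(oracle_midrank(x), oracle_midrank(y[p])))
    if (s >= obs - 1e-12) hits <- hits + 1
  }
  hits / length(perms)
}

oracle_signflip_pvalue <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  obs <- abs(mean(d))
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1, 1)
    if (abs(mean(d * signs)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / 2^n
}

# trapezoid-free direct summation of a sampled function over a window
oracle_sampled_mean <- function(f, start, end, fs) {
  t <- start
  total <- 0
  count <- 0
  while (t < end - 1e-12) {
    total <- total + f(t)
    count <- count + 1
    t <- t + 1 / fs
  }
  total / count
}

# convenience: constant + signal trace builders
make_trace <- function(values, fs = 50, channel = "tongue", t0 = 0) {
  pressure_trace(values, fs = fs, channel = channel, t0 = t0)
}
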