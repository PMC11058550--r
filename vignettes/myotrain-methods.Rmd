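---
title: "Models and design of the myotrain training engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the myotrain training engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrain)
```

This vignette documents the scientific models behind the package, the
parameters that matter, the numerical conventions, and the decisions that
were genuinely open when the engine was designed.

## The measurement model

The device reads absolute pressure from two cavities in a silicone
mouthpiece — one loaded by the lips, one by the tip of the tongue — and
digitises each channel at a fixed rate. A `pressure_trace` is the package's
universal signal: an ordered vector of kPa readings with a sampling rate
`fs` and start time, sample `i` living at `t0 + (i-1)/fs`.

**Sampling rate.** The device's electronics do not dictate a specific rate
to the software layer; the package default is `fs = 50` Hz. The choice is
driven by the scoring resolution: the scored phase of a tracking cycle is
1.5 s, so 50 Hz yields 75 samples per scored window and a worst-case
one-sample truncation error below 1.5% of a cycle score.

**Windows and bands.** Scoring windows are half-open `[start, end)` so that
consecutive cycles tile the timeline without double-counting boundary
samples. Pressure-band membership is closed (`lo ≤ p ≤ hi`): a reading
sitting exactly on the displayed box edge counts as in range. All fractions
are computed sample-wise, never by interpolating threshold crossings — this
matches what a sampled digital device can actually measure and keeps the
scores exactly reproducible from a logged trace.

## Calibration

**Zero calibration.** The mouthpiece warms from room to mouth temperature
after insertion, and the sealed cavity pressure drifts with it. The
simulator models the drift as first order,
$b(t) = b_\infty\,(1 - e^{-t/\tau})$ with $\tau = 20$ s, putting the
baseline within 5% of its asymptote after one minute — which is why the
protocol runs a zero calibration at insertion, a two-minute warm-up game,
and a second, authoritative zero calibration afterwards. The offset is the
mean over the final 2 s of a released-pressure epoch; the corrected trace
is simply `apply_offset(trace, offset)`.

**Maximal pressure.** Each channel's reference `Pmax` comes from three
consecutive maximal efforts. With attempt peaks $p_i$ and mean $m$, the
round is accepted iff $\max_i |p_i - m| / m \le 0.075$, and $m$ becomes
`Pmax`. Three readings of that rule were open:

- *Which deviation?* "Absolute deviation" is implemented as the **maximum**
  absolute deviation over the three peaks — the strictest reading; a
  mean-absolute-deviation variant is available via
  `calibration_policy(dev_stat = "mean")`.
- *The boundary.* A relative deviation of exactly 7.5% is **accepted**: the
  procedure repeats only when the deviation is strictly greater.
- *What repeats?* The whole three-attempt round is redone, not just the
  outlying attempt, up to `max_rounds = 5`; an exhausted budget returns an
  unaccepted record (the session is then marked incomplete) rather than
  raising an error.

## Task scoring

A tracking cycle is 8 s rest + 3 s target; the first 1.5 s of the target
phase are an unscored reaction window. The target band defaults to 3–5% of
`Pmax` — deliberately light contractions aimed at endurance, not strength.
The cycle score is the fraction of scored samples inside the absolute band
`[0.03, 0.05] · Pmax`, and the task score is 100 × the mean over 10 cycles
(equivalently pooled time-in-band, since scored windows share one length).
Two open points were resolved as follows: the "green box" is the full 3–5%
band rather than a random level per cycle, and behaviour during rest is
logged (mean rest pressure per cycle) but never scored or penalised.

The breathing task asks for a continuous lip pressure of at least 4% of
`Pmax` for 7 × 16 s breathing cycles; the on-screen inhale/exhale pacing is
display-only, so the score is simply the above-threshold time fraction over
the whole 112 s.

## Games

The four games are motivational filler between metered exercises, and
their scores are excluded from the success analytics. The mechanics are
fixed (paddle bounce counter with speed growth; 3 s dwell inside a
shrinking, relocating circle against a 30 s countdown that gains 7 s per
success; press-and-release missile launches at a six-colour wheel; a
press-release-steered hole in a wall), but none of the numeric constants
are published values — speeds, the 0.2 paddle length, the 0.15 → ×0.9
(floor 0.05) circle radius schedule, the 2%/1% press-release hysteresis
thresholds and the 0.1 hole increment are device configuration, declared
in `game_rules()`. Each game advances on a fixed timestep `1/fs` and draws
respawn positions from R's seeded RNG, so a run replays bit-identically
from `(rules, controller, seed)`; the high score is a running maximum and
the test suite checks ball containment in the unit field under random
play.

## The session protocol

A session is: zero cal → 2-min warm-up game → zero cal → max cal (tongue,
then lips) → 4 × [zero cal, breathing, lip task, tongue task, game]. The
default plan therefore holds 4 breathing, 4 lip and 4 tongue tasks, 4
post-warm-up games, 6 zero calibrations and 2 maximal calibrations, and
its scheduled duration (~34 min) sits inside the program's nominal
35 minutes. "Zero calibration repeated before each training session" was
ambiguous between per-round and per-task; per-round is the default and
`session_config(zero_cal_per_task = TRUE)` flips it. The warm-up game
defaults to the paddle game; round games rotate through all four variants
in a seeded order. A session is *completed*, for compliance purposes, iff
all 12 tasks produced scores and both maximal calibrations were accepted —
partial sessions are logged but not counted. Logs are schema-versioned
JSON and round-trip field-for-field.

## The participant simulator

The simulator exists to give every module statistically structured inputs,
and its defaults are the conditions of the 4-week evaluation program:
6 prescribed sessions/week for 4 weeks, ~91% attendance, and roughly a 20%
four-week dropout rate (geometric daily hazard 0.008).

**Learning.** The per-sample in-band probability ("skill") follows a
saturating exponential in training days,
$s(d) = s_\infty - (s_\infty - s_0)\,e^{-d/\kappa}$ with $\kappa = 9$
days. Defaults are per-task ($s_0$ = 0.635/0.769/0.847 and $s_\infty$ =
0.860/0.875/0.965 for tongue/lip/breathing), chosen so the cohort's
expected day-1 and day-28 scores land near the observed 66→85%, 78→87% and
86→96% trajectories.

**Noise inversion.** During a target phase the simulated pressure rises
first-order (latency 0.8 s, rise constant 0.15 s) to the band centre and
carries Gaussian noise. The noise SD is *derived from* the programmed
skill: with band half-width $h$ (in kPa) and target in-band probability
$s$, $\sigma = h / \Phi^{-1}((1+s)/2)$, so that
$P(|p - \text{centre}| \le h) = s$ per sample. The breathing task inverts
the same way around its threshold: the held level is
$0.04\,P_{max} + \Phi^{-1}(s)\,\sigma_0$ with fixed
$\sigma_0 = 0.01\,P_{max}$. This is what makes parameter recovery exact in
expectation: a user programmed at skill 0.7 scores 70% on average, which
the acceptance suite verifies over 200 simulated cycles (binomial
tolerance ±3).

**Maximal-pressure attempts** are lognormal around the participant's true
maximum (CV 2.5%), occasionally tripping the 7.5% rule and exercising the
repeat loop. Scoring targets always use the *calibrated* `Pmax` — the
participant tracks the displayed box, so calibration error does not bias
the in-band probability.

**Cohort covariates.** Synthetic pre/post clinical covariates are attached
per cohort. The change in supine AHI is coupled to each participant's
simulated lip-score improvement through a Gaussian copula: the latent
correlation is $\rho = 2\sin(\pi r_s/6)$ so that the programmed Spearman
$r_s$ (default −0.76, the observed association's magnitude and sign) is
exact in expectation, and $r_s = \pm 1$ degenerates to exactly (reversed)
ranks. The change is mapped through one common strictly monotone quantile
transform — a normal truncated below at $-\min(\text{pre})$ — so post
values stay non-negative *without clipping*, which would otherwise break
the programmed rank coupling.

**What the simulator does not emulate.** Respiratory waveforms, airway
mechanics, fatigue within a session, correlated noise (tremor), strategic
behaviour (gaming the band edge), or any causal link between training and
AHI — the programmed covariate association is a statistical coupling for
pipeline testing, not a physiological claim. Passing recovery tests
therefore validates the software chain, not the therapy.

## Analytics conventions

- Compliance = completed sessions / 24 prescribed; pooled compliance is
  total completed over total prescribed (equal to the participant mean
  when denominators are equal, which the tests assert).
- "First day"/"last day" are each participant's first and last *completed*
  sessions; the day value is the mean of that session's (up to 4) scores
  of the task kind.
- The 96% interval is reported exactly as the evaluation reports it:
  mean ± 1.96 SD of the raw values. That is a dispersion band, not a
  standard-error confidence interval, and every `success_summary` carries
  a `ci_is_dispersion_band` flag saying so.
- Report rounding is half-away-from-zero (`round_half_up()`): whole
  percent for success/compliance, one decimal for AHI. Base R's
  round-half-even disagrees with the clinical tables at exact halves
  (e.g. 86.75 → 87, 17.725 → 17.7).
- Spearman correlation uses midranks for ties and errors on constant
  input. Inference is by permutation: exhaustive over all $n!$
  permutations for $n \le 8$ (seed-independent, $p \ge 1/n!$), seeded
  Monte-Carlo with an identity-inclusion correction above. Pre/post
  comparisons use an exact sign-flip permutation test on paired
  differences (all $2^n$ patterns for $n \le 20$). This is deliberately
  *not* a random-intercept mixed model; the package makes no attempt to
  reproduce mixed-model P values.

## Numerical and testing choices

Degenerate inputs are pinned down explicitly: empty window overlap, traces
shorter than a schedule, non-positive attempt peaks, `react_s ≥ target_s`
(empty scored window), constant vectors in correlations, and rounds = 0
all raise informative errors; an exhausted calibration source yields an
unaccepted record instead. Seeds derived internally stay below $2^{31}$.
Ball reflections fold positions back into the unit field, and speeds are
capped (default 5 field units/s) so one timestep never jumps a wall.

Test and acceptance runs scale simulation sizes to keep the suite fast
while leaving every tolerance untouched: skill recovery uses one
200-cycle task; attendance recovery uses 50 participants × 24 prescribed
sessions with single-round sessions and 5 s games (attendance, the
measured quantity, is independent of per-session content); the
association cohort uses 8 participants with full 4-round sessions, whose
4-task daily averages give improvement scores a fine enough grid that
rank ties are unlikely. Scoring equivalence is checked against an
independent per-sample loop oracle over a 10× denser resampling of
analytic signals, on 100 random sinusoid traces (tolerance 2 percentage
points, dominated by genuine band-crossing discretisation).

## Known limitations

- The band-edge behaviour of a real ADC (quantisation, anti-alias
  filtering) is not modelled; traces are ideal samples.
- The thermal model is a single first-order pole; real mouthpieces may
  show slower creep, which the post-warm-up zero calibration absorbs only
  partially.
- Game physics constants are plausible defaults, not measurements; only
  the published mechanics (counters, timers, dwell and growth rules) are
  fixed points.
- The breathing-task group trajectory and the supine-AHI association are
  represented in the simulator by programmed parameters, not recoverable
  from published per-participant data; they are validated by property
  tests (parameter recovery, forced-association inference), not by value
  reproduction.
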