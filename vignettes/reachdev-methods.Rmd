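---
title: "Models and methods behind reachdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reachdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachdev)
library(dplyr)
```

## The scientific problem

Goal-directed reaching can succeed through two complementary mechanisms:
*feedforward adaptation*, a slow trial-to-trial recalibration of the planned
movement direction driven by experienced error, and *online feedback
control*, within-movement steering using visual error. Children and adults
differ systematically in how much they rely on each, and this package
provides the full analysis chain for quantifying that developmental
trade-off in gradual visuomotor-rotation games played with a mouse,
trackpad or touchscreen:

* the **paradigm**: trial schedules, the ramped 30° clockwise rotation, the
  error-clamp block and hit/miss logic for two tasks — *Push ball* (the
  ball follows the hand throughout, so both mechanisms are available) and
  *Launch ball* (the ball flies along the launch direction, so only
  adaptation can succeed);
* a **synthetic cohort generator**: age-parameterised state-space learners
  that produce full raw sessions with realistic polling, timing and noise,
  so every downstream stage is exercisable and testable without access to
  participant data;
* **kinematics**: every per-trial measure (initial, final, launch,
  compensation angle; path-length ratio; correction point and normalised
  correction time; angle spread; reaction/stationary/movement times);
* **epochs and developmental fits**: window averages and the
  inverse / logarithmic / exponential age models;
* **reference curves**: LMS (Box-Cox Cole-Green) age-conditional
  percentile curves with AIC family selection and quantile-residual
  diagnostics.

## The paradigm in numbers

A Push ball session has 160 trials (20 baseline, 90 learning, 20 error
clamp, 30 washout); Launch ball has 40 baseline trials (it is the less
naturalistic task, so more familiarisation) for 180 in total. During
learning the rotation ramps at 0.5°/trial for 60 trials — the first ramp
trial already applies −0.5°, so trial 60 reaches the full −30° — and is
held for 30 more. Clockwise angles are negative throughout; full
compensation of the −30° rotation means aiming the hand at +30°. The start
sits at the origin, the target centre 24 game units (GU) straight ahead,
and a trial is a hit when the displayed ball ends within ±10° of the
target centre (boundary inclusive).

During the error clamp the displayed ball ignores the hand direction and
moves at a small random angle drawn uniformly from ±2° each trial (we take
the quoted range as a uniform distribution; nothing finer is specified).
Every clamp trial therefore succeeds, and the hand direction reveals the
retained adaptation — the aftereffect. The published block arithmetic
("trials 110–130" for the clamp, 21 indices for a 20-trial block) is
ambiguous by one trial; we adopt clamp = trials 111–130, the unique
assignment consistent with all four block lengths.

## The synthetic participant

The study fits no generative model, so the generator is this package's own
minimal mechanism reproducing the reported structure. Each participant is
a single-rate state-space learner with within-trial proportional steering:

* state update: \(x_{n+1} = A x_n - B e_n\), with retention \(A = 0.98\)
  and learning rate \(B\); the error \(e_n\) is the displayed angle at the
  initial-angle threshold point (clamp trials: the clamp jitter), so
  feedback corrections do not contaminate the teaching signal;
* plan: \(p_n = x_n + \varepsilon\), \(\varepsilon \sim N(0,
  \sigma_\text{plan}^2)\);
* steering (Push ball, non-clamp only): after a visual-delay fraction
  (default 0.25 of the movement extent, reflecting ~150–180 ms visual
  delays relative to child movement times) the heading blends smoothly
  toward the hand angle that zeroes displayed error, closing a fraction
  \(G\) of the gap by movement end; Launch ball and clamp trials steer not
  at all.

Age enters through the targets the parameters are solved from. The
end-of-learning adaptation (initial angle) of a participant aged `age_mo`
months targets \(a + b/\text{age}\) with \(a = 25.16\)°, \(b = -720.9\)
°·months, and overall performance (final angle) targets \(a = 29.7\)°,
\(b = -295.3\), both clipped to [0, 30]. \(B\) is solved numerically so
the deterministic learner's mean state over the last 10 learning trials
equals the (participant-jittered) adaptation target; \(G = (\text{FA
target} - \text{IA target})/(30 - \text{IA target})\), so younger children
— who adapt little — steer more, filling the success gap with feedback.
Between-participant jitter of the targets is multiplicative log-normal
(sdlog 0.12 and 0.08), which keeps a zero target exactly zero and avoids
clipping bias at young ages; jittered adaptation targets are capped at 29°
because the \(A = 0.98\) learner cannot exceed \(30B/(1-A+B) < 29.42\)° at
the end of learning.

Noise and timing decrease monotonically with age (planning sd
\(1.5 + 6e^{-0.010\,\text{age}}\)°, execution sd
\(0.8 + 2.2e^{-0.010\,\text{age}}\)°, movement time
\(900 + 1800e^{-0.008\,\text{age}}\) ms, and similar laws for reaction and
stationary time, each with 15% log-normal participant jitter). These
shapes are our choices: exponentials in age are the same family the
variability analyses use, and the endpoints (e.g. ~2.4 s child vs ~1.1 s
adult movement times, ~6° child vs ~2° adult planning sd) sit in the range
the developmental literature reports for this kind of task. Input-device
polling is emulated at a jittered ~60 Hz with 20% i.i.d. multiplicative
spacing noise; stationary periods produce no samples. Device and sex are
carried as metadata only — the reported device effect has no usable
magnitudes to simulate.

Each participant draws from a private seeded stream derived from the
cohort seed and participant index, so cohorts are reproducible and
order-independent; ages are uniform over the configured range (default
36–216 months) unless given explicitly.

**What the generator does not emulate**: explicit re-aiming strategies,
two-rate (fast/slow) learning, device biomechanics, attentional lapses,
session breaks, and real home-computer artifacts beyond polling jitter.
Passing parameter-recovery tests therefore shows the pipeline is correct
and well-calibrated on data with this structure — not that the
developmental conclusions would replicate on any particular real cohort.

## Kinematic definitions and numerical choices

The movement angle of a sample is the signed angle between the
start-to-sample chord and the start-to-target line (counterclockwise
positive) — chords, not instantaneous velocity, are used everywhere. The
initial angle is taken at the first sample at least 1.2 GU (5% of the
target distance) from the start; we use straight-line distance from the
start (the stricter, order-independent reading) with the along-path
variant available via `metric = "path"`. The final angle is the chord to
the last sample; the launch angle is computed identically. Compensation =
final − initial, exactly. The correction scan starts strictly after the
initial-angle sample (the IA sample cannot be its own correction point)
and reports the first sample whose movement angle leaves the IA ± 5°
window, normalised by movement time. Movement onset is the first sample
with nonzero displacement after the click — no velocity threshold, because
raw polled positions are analysed without smoothing. `ia_time_ms` is
referenced to movement onset, and so labelled.

Trials whose trajectory never reaches the threshold or is degenerate are
flagged invalid with a reason, excluded from epoch means with the trial
count decremented (drop-and-decrement, no imputation), and counted in the
QC trail.

## Epochs and developmental fits

Epoch windows: last 10 baseline trials, last 10 learning trials, first/last
3 clamp trials, first 3 and last 10 washout trials — fewer trials where
rapid change is expected. Ages are in months everywhere a formula sees
them (plots may label years; months = years × 12). Adults are flagged at
≥ 216 months and excluded from all curve fits but kept in summaries.

Three two-parameter age models are provided: inverse \(a + b/\text{age}\)
(the default: it plateaus, which is biologically sensible), logarithmic
\(a\log(\text{age}) + b\), and exponential \(a e^{b\,\text{age}}\) (used
for standard deviations and the compensation angle). The exponential fit
is nonlinear least squares with a deterministic start from a log-linear
regression of \(|y|\) on age, and a `scaleOffset` in the convergence test
so exact (zero-residual) data converge. Confidence intervals are 95% Wald
intervals and are labelled as such — a profile-based tool may give
slightly different intervals for the nonlinear fit. Model selection takes
the highest adjusted R², breaking exact ties toward the inverse model.

## LMS reference curves

`fit_lms()` maximises the likelihood of the NO (normal) or BCCG (Box-Cox
Cole-Green) family with each parameter a natural cubic spline function of
age: default 3 df for the median and coefficient of variation, 1 for the
Box-Cox power (df = 0 means age-constant). We use the untruncated
Cole-Green density — standard LMS practice; the truncation mass is
negligible at the coefficients of variation seen here. AIC is
\(-2\ell + 2 \times \text{total df}\), with total df the count of free
coefficients; the normal family has its power fixed at 1 with 0 df.
Optimisation is BFGS from a deterministic start (power 1, median from a
smooth mean fit, spread from residuals), with a Nelder-Mead polish if
BFGS reports non-convergence, so fits are seed-free. BCCG requires
strictly positive responses; zeros or negatives trigger an automatic,
warned fallback to the normal family. Kurtosis-modelling families (BCT,
BCPE) are out of scope; when BCCG residual diagnostics show kurtosis the
moment table says so and the limitation stands.

Percentile curves map standard-normal quantiles back through the fitted
parameters; they cannot cross in level at a given age because the map is
strictly monotone. Diagnostics are normalised quantile residuals
\(\Phi^{-1}(F(y\,|\,\text{age}))\) with first-four-moment z-statistics in
nine equal-count age groups (the published nine "data-driven" groups are
not specified further; equal-count is our labelled choice). The sampling
variance of the estimated Box-Cox power is substantial (sd ≈ 0.15 even at
n = 2,000 with a 15% coefficient of variation), so recovery checks
average the MLE over replicate datasets rather than trusting one draw.
Outliers are removed only via an explicit user-supplied exclusion list —
no automatic rejection. For sex-stratified curves the intended procedure
is: select the family on pooled data, then refit per stratum with that
family, which `select_family()` plus `fit_lms()` compose directly.

## The pipeline

`run_pipeline()` chains simulate → qc → extract → epochs → fits →
centiles under the single cohort seed and writes every artifact
(`sessions.jsonl`, `qc_report.csv`, `measures.csv`, `epochs.csv`,
`fits.json`, `centiles.csv`, `log.txt`). Reruns are byte-identical except
log timestamps; no stage reads the wall clock for computation. QC mirrors
the study's review: sessions over 2 h, median movement-phase polling below
20 Hz, or incomplete sessions are excluded, each exclusion logged with its
rule. Sessions serialise as JSON lines, one trial per line, with numerics
quantised to 6 fractional digits at simulation time so round-trips are
exact; `.gz` paths compress transparently.

## Problem sizes used in the test suite

The suite checks the kinematics against independent brute-force oracles on
500 random trajectories, the simulator against the closed-form scalar
recursion exactly and against the retention factor over 1,000 clamp
phases, end-to-end parameter recovery on one default 200-participant
cohort (shared across test files), LMS recovery over 40 replicate
datasets of n = 2,000, and the clamp signatures on 30 adult sessions.
These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping the whole suite under a few minutes.

## A small worked example

```{r example, eval = FALSE}
co <- cohort_config(n_participants = 50, seed = 1)
sessions <- simulate_cohort(co, task = "pushball")
measures <- extract_measures(sessions)
epochs <- extract_epochs(measures)

children <- epochs |>
  filter(epoch == "end_learning", measure == "initial_angle_deg", age_mo < 216)
fit <- fit_inverse(children, mean)
tidy(fit)
autoplot(fit)

lms <- select_family(
  children |> select(age_mo, y = mean), y,
  df = c(mu = 2, sigma = 1, lambda = 0)
)
percentile_curve(lms, levels = c(5, 50, 95))
```

## Known limitations

* The generator is a single-rate learner: it reproduces gradual learning,
  clamp retention and washout decay, but not fast/slow dissociations or
  savings.
* Wald intervals for the exponential fit; profile or bootstrap intervals
  are not implemented.
* LMS families stop at BCCG; heavy-tailed measures will show residual
  kurtosis that the model cannot absorb.
* The clamp block's one-trial index ambiguity (111–130 adopted) is a
  reading, not established fact; all epoch code keys off block labels, so
  a different assignment would shift windows consistently.
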