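# reachdev

Tools for quantifying how **feedforward adaptation** and **online feedback
control** develop through childhood in gradual visuomotor-rotation reaching
games, for motor-learning and developmental researchers.

In these games a participant moves a ball from a start position to a target
24 game units (GU) straight ahead. Across the learning block a 30° clockwise
rotation is ramped in between hand and ball (0.5°/trial over 60 trials, then
held for 30); an error-clamp block then shows the ball moving nearly straight
at the target (±2° jitter) regardless of the hand, revealing the retained
adaptation, before a washout. Two tasks separate the mechanisms: *Push ball*
(the ball follows the hand, so within-movement steering can rescue a poorly
adapted plan) and *Launch ball* (the ball flies along the launch direction,
so only adaptation can succeed).

The package provides, as tidyverse-style data-frame-in / tibble-out
functions:

* **Paradigm** — `build_schedule()`, `displayed_angle()`,
  `evaluate_trial()`, `hand_success_zone()`: the trial program, clamp logic
  and the ±10° success window.
* **Synthetic cohort** — `cohort_config()`, `default_age_params()`,
  `simulate_trial()`, `simulate_cohort()`: age-parameterised single-rate
  state-space learners, `x' = A x − B e` with retention `A = 0.98`, whose
  end-of-learning adaptation follows the inverse-age law
  `a + b/age_mo` (`a = 25.16°`, `b = −720.9°·mo`) and whose feedback gain
  fills the gap to the overall-performance law (`a = 29.7°`,
  `b = −295.3°·mo`); full raw sessions with realistic polling and timing.
* **Kinematics** — `extract_measures()` and the per-trajectory functions
  (`initial_angle()`, `final_angle()`, `launch_angle()`,
  `path_length_ratio()`, `correction_metrics()`, `angle_spread()`,
  `timing_measures()`): every per-trial measure, with invalid trials
  flagged and reasoned.
* **Epochs & developmental fits** — `extract_epochs()`,
  `variability_summary()`, `fit_inverse()`, `fit_log()`,
  `fit_exponential()`, `select_model()`, with broom-style `tidy()` /
  `glance()` and `autoplot()`.
* **Reference curves** — `fit_lms()`, `select_family()`,
  `percentile_curve()`, `quantile_residuals()`: LMS (Box-Cox Cole-Green or
  normal) age-conditional percentile curves with AIC family selection and
  quantile-residual moment diagnostics.
* **IO, QC and pipeline** — `write_sessions()` / `read_sessions()` (JSONL,
  lossless), `apply_qc()` (2-hour duration, polling-rate and completion
  rules), `run_pipeline()` (simulate → qc → extract → epochs → fits →
  centiles under one seed, byte-reproducible artifacts).

See `vignettes/reachdev-methods.Rmd` for the models, assumptions, numerical
choices and limitations.

## Worked example

Simulate a 50-child cohort, score every trajectory, summarise the
end-of-learning epoch and fit the developmental laws:

```r
library(reachdev)
library(dplyr)

co <- cohort_config(n_participants = 50, seed = 1)
sessions <- simulate_cohort(co, task = "pushball")
measures <- extract_measures(sessions)
epochs <- extract_epochs(measures)

children <- epochs |>
  filter(epoch == "end_learning", measure == "initial_angle_deg", age_mo < 216)
fit_inverse(children, mean)
#> <devcurve_fit> inverse model: a = 26.55 (25.19, 27.91), b = -775 (-878.8, -671.1)
#>   adjusted R^2 = 0.821, n = 50

comp <- epochs |>
  filter(epoch == "end_learning", measure == "compensation_angle_deg", age_mo < 216)
fit_exponential(comp, mean)
#> <devcurve_fit> exponential model: a = 18.59 (14.73, 22.46), b = -0.007501 (-0.00986, -0.005141)
#>   adjusted R^2 = 0.506, n = 50
```

The inverse fit says adaptation (the initial angle at the end of learning)
plateaus near 26.5° in adolescence and is `775/age_mo` degrees lower in
younger children — a 4-year-old (48 mo) adapts only ~10° of the 30°
rotation. The exponential fit shows the compensation angle — the
within-movement feedback correction — decaying with age: young children
steer to the target, adolescents barely need to. `autoplot()` on either
fit draws the data and curve; `tidy()`/`glance()` return the coefficient
and fit tables.

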