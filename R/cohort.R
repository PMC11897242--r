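#' Synthetic cohort configuration
#'
#' Defaults encode the developmental structure the simulator emulates: the
#' end-of-learning adaptation (initial angle) of a participant of age
#' `age_mo` months targets `a + b / age_mo` with `a = 25.16`, `b = -720.9`
#' degrees, and the overall performance (final angle) targets `a = 29.7`,
#' `b = -295.3`, both clipped to \[0, 30\]. Younger children therefore adapt
#' less and fill the gap with online feedback corrections.
#'
#' @param n_participants Number of synthetic participants.
#' @param age_range_mo Two-element age interval in months (children 36-216;
#'   ages at or above 216 are treated as adults downstream).
#' @param ages_mo Optional explicit age vector (overrides `age_range_mo`).
#' @param inverse_curve_a_deg,inverse_curve_b_deg_mo Target inverse-age law
#'   for end-of-learning adaptation (degrees; degree-months).
#' @param fa_curve_a_deg,fa_curve_b_deg_mo Same for overall performance.
#' @param retention_A Trial-to-trial retention of the single-rate learner.
#' @param ia_jitter_sdlog,fa_jitter_sdlog Log-scale between-participant jitter
#'   of the two targets.
#' @param seed Integer master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 200,
                          age_range_mo = c(36, 216),
                          ages_mo = NULL,
                          inverse_curve_a_deg = 25.16,
                          inverse_curve_b_deg_mo = -720.9,
                          fa_curve_a_deg = 29.7,
                          fa_curve_b_deg_mo = -295.3,
                          retention_A = 0.98,
                          ia_jitter_sdlog = 0.12,
                          fa_jitter_sdlog = 0.08,
                          seed = 1) {
  if (!is_scalar_number(n_participants) || n_participants < 1) {
    abort("`n_participants` must be at least 1.", class = "reachdev_bad_config")
  }
  if (length(age_range_mo) != 2 || age_range_mo[1] < 36 || age_range_mo[2] > 600 ||
    age_range_mo[1] > age_range_mo[2]) {
    abort("`age_range_mo` must lie within [36, 600].", class = "reachdev_bad_config")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      age_range_mo = as.numeric(age_range_mo),
      ages_mo = ages_mo,
      inverse_curve_a_deg = inverse_curve_a_deg,
      inverse_curve_b_deg_mo = inverse_curve_b_deg_mo,
      fa_curve_a_deg = fa_curve_a_deg,
      fa_curve_b_deg_mo = fa_curve_b_deg_mo,
      retention_A = retention_A,
      ia_jitter_sdlog = ia_jitter_sdlog,
      fa_jitter_sdlog = fa_jitter_sdlog,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Target developmental laws of the generator
#'
#' The deterministic (pre-jitter) inverse-age targets for end-of-learning
#' adaptation and overall performance, clipped to \[0, 30\] degrees.
#'
#' @param age_mo Age(s) in months.
#' @param cohort A [cohort_config()].
#' @return Degrees.
#' @export
adaptation_target <- function(age_mo, cohort = cohort_config()) {
  clip(cohort$inverse_curve_a_deg + cohort$inverse_curve_b_deg_mo / age_mo, 0, 30)
}

#' @rdname adaptation_target
#' @export
performance_target <- function(age_mo, cohort = cohort_config()) {
  clip(cohort$fa_curve_a_deg + cohort$fa_curve_b_deg_mo / age_mo, 0, 30)
}

# Deterministic single-rate state recursion over the learning block:
# x_{k+1} = A x_k - B (x_k + r_k), x_1 = 0. Returns the mean state over the
# last 10 learning trials (the end-of-learning epoch).
deterministic_end_learning <- function(B, A, rotations) {
  x <- 0
  xs <- numeric(length(rotations))
  for (k in seq_along(rotations)) {
    xs[k] <- x
    x <- A * x - B * (x + rotations[k])
  }
  mean(tail(xs, 10))
}

# Smallest learning rate whose deterministic end-of-learning adaptation hits
# the target. Monotone in B on [0, 1]; target must be below the A-limited
# ceiling 30 B / (1 - A + B).
solve_learning_rate <- function(target_deg, A, rotations) {
  if (target_deg <= 0) {
    return(0)
  }
  f <- function(B) deterministic_end_learning(B, A, rotations) - target_deg
  if (f(1) < 0) {
    abort("Adaptation target exceeds what the single-rate learner can reach.",
      class = "reachdev_target_unreachable"
    )
  }
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

learning_rotations <- function() c(-0.5 * seq_len(60), rep(-30, 30))

#' Age-parameterised generative participant
#'
#' Maps age to the parameters of a synthetic participant: retention fixed at
#' `A = 0.98`; learning rate `B` solved so the deterministic single-rate
#' learner's end-of-learning adaptation equals the (jittered) inverse-age
#' target; feedback gain `G` set so the expected final angle approaches the
#' overall-performance target; planning and execution noise and all timing
#' means decrease monotonically with age; input-device polling rate jittered
#' around 60 Hz. All jitter is drawn from a generator seeded with `seed`, so
#' the same (age, seed) pair always yields the same participant.
#'
#' @param age_mo Age in months (36 or older).
#' @param cohort A [cohort_config()].
#' @param seed Integer seed for the participant-level jitter.
#' @param participant_id Identifier carried through the pipeline.
#' @return A one-row tibble of class `participant_params`.
#' @export
default_age_params <- function(age_mo, cohort = cohort_config(), seed = 0L,
                               participant_id = "P001") {
  if (!is_scalar_number(age_mo) || age_mo < 36) {
    abort("`age_mo` must be at least 36 months (the youngest studied age).",
      class = "reachdev_age_range"
    )
  }
  A <- cohort$retention_A
  ia0 <- adaptation_target(age_mo, cohort)
  fa0 <- performance_target(age_mo, cohort)
  draws <- withr::with_seed(as.integer(seed), {
    list(
      ia_jit = exp(rnorm(1, 0, cohort$ia_jitter_sdlog)),
      fa_jit = exp(rnorm(1, 0, cohort$fa_jitter_sdlog)),
      sd_jit = exp(rnorm(2, 0, 0.15)),
      t_jit = exp(rnorm(3, 0, 0.15)),
      poll_jit = exp(rnorm(1, 0, 0.10)),
      device = sample(c("mouse", "trackpad", "touchscreen"), 1,
        prob = c(0.6, 0.25, 0.15)
      ),
      sex = sample(c("F", "M"), 1)
    )
  })
  # the A = 0.98 learner cannot exceed ~29.4 deg at end of learning; cap the
  # jittered target safely below that ceiling
  ia_t <- min(ia0 * draws$ia_jit, 29)
  fa_t <- clip(fa0 * draws$fa_jit, ia_t, 30)
  B <- solve_learning_rate(ia_t, A, learning_rotations())
  G <- if (30 - ia_t < 1e-8) 0 else clip((fa_t - ia_t) / (30 - ia_t), 0, 1)
  tibble(
    participant_id = participant_id,
    age_mo = age_mo,
    retention_A = A,
    learning_rate_B = B,
    feedback_gain_G = G,
    plan_sd_deg = (1.5 + 6 * exp(-0.010 * age_mo)) * draws$sd_jit[1],
    motor_sd_deg = (0.8 + 2.2 * exp(-0.010 * age_mo)) * draws$sd_jit[2],
    rt_mean_ms = (450 + 700 * exp(-0.008 * age_mo)) * draws$t_jit[1],
    st_mean_ms = (120 + 300 * exp(-0.008 * age_mo)) * draws$t_jit[2],
    mt_mean_ms = (900 + 1800 * exp(-0.008 * age_mo)) * draws$t_jit[3],
    polling_hz = clip(60 * draws$poll_jit, 25, 120),
    device = draws$device,
    sex = draws$sex
  )
}

smoothstep <- function(u) {
  u <- clip(u, 0, 1)
  u * u * (3 - 2 * u)
}

#' Simulate one trial
#'
#' Generates one hand trajectory and the trial-to-trial state update of the
#' single-rate learner. The movement plan is the current adapted state plus
#' planning noise. In Push ball (outside the clamp) the heading steers, after
#' a visual-delay fraction of the movement, toward the hand angle that zeroes
#' the displayed error, closing a fraction `G` of the gap by movement end and
#' producing a curved path; in Launch ball and on clamp trials no steering
#' occurs. Samples arrive at the participant's polling rate with 20%
#' multiplicative interval jitter; Push ball paths terminate when the
#' displayed ball crosses the target plane (y = 24 GU). The state updates as
#' `x' = A x - B e`, where `e` is the displayed angle at the initial-angle
#' threshold point (clamp trials: the clamp jitter). Uses the caller's RNG
#' state; seed it for reproducibility.
#'
#' @param state_deg Current adapted state, degrees.
#' @param spec One schedule row.
#' @param params A [default_age_params()] row (or compatible list).
#' @param task `"pushball"` or `"launchball"`.
#' @param t_start_ms Absolute trial start time, ms.
#' @param visual_delay_frac Fraction of the movement before steering begins.
#' @param target_distance_gu Start-to-target distance, game units.
#' @param ia_threshold_gu Distance at which the teaching error is read.
#' @return List with `samples` (matrix `t_ms`, `x_gu`, `y_gu`; first row at
#'   the origin), `t_trial_start_ms`, `t_click_ms`, `error_deg`,
#'   `next_state_deg`.
#' @export
simulate_trial <- function(state_deg, spec, params, task = "pushball",
                           t_start_ms = 0, visual_delay_frac = 0.25,
                           target_distance_gu = 24, ia_threshold_gu = 1.2) {
  task <- check_task(task)
  p <- state_deg + rnorm(1, 0, params$plan_sd_deg)
  rt <- params$rt_mean_ms * exp(rnorm(1, 0, 0.20))
  st <- params$st_mean_ms * exp(rnorm(1, 0, 0.30))
  mt <- params$mt_mean_ms * exp(rnorm(1, 0, 0.20))
  t_click <- t_start_ms + rt
  t_onset <- t_click + st

  steer <- task == "pushball" && !isTRUE(spec$clamp)
  h_star <- -spec$rotation_deg
  G <- if (steer) params$feedback_gain_G else 0
  f <- p + G * (h_star - p) + rnorm(1, 0, params$motor_sd_deg)

  base_dt <- 1000 / params$polling_hz
  n <- max(6L, as.integer(round(mt / base_dt)))
  dt <- base_dt * pmax(rnorm(n - 1, 1, 0.2), 0.3)
  t <- t_onset + c(0, cumsum(dt))
  u <- (t - t[1]) / (t[n] - t[1])

  theta <- p + (f - p) * smoothstep((u - visual_delay_frac) / (1 - visual_delay_frac))
  if (n > 2) {
    theta[2:(n - 1)] <- theta[2:(n - 1)] + rnorm(n - 2, 0, 0.4 * params$motor_sd_deg)
  }

  # extent so the displayed ball just crosses the target plane (Push ball);
  # Launch ball hand paths cover roughly the start-target distance
  disp_final <- if (isTRUE(spec$clamp)) f else f + spec$rotation_deg
  ref <- if (task == "pushball" && !isTRUE(spec$clamp)) disp_final else f
  R <- target_distance_gu * 1.001 / max(cos(deg2rad(clip(ref, -60, 60))), 0.5)
  r <- R * u

  xy <- angle_to_xy(theta, r)
  xy[1, ] <- c(0, 0)
  samples <- cbind(t_ms = round(t, 6), x_gu = round(xy[, 1], 6), y_gu = round(xy[, 2], 6))

  if (isTRUE(spec$clamp)) {
    e <- spec$clamp_jitter_deg
  } else {
    ia_idx <- which(r >= ia_threshold_gu)[1]
    e <- if (is.na(ia_idx)) f + spec$rotation_deg else theta[ia_idx] + spec$rotation_deg
  }
  next_state <- params$retention_A * state_deg - params$learning_rate_B * e

  list(
    samples = samples,
    t_trial_start_ms = round(t_start_ms, 6),
    t_click_ms = round(t_click, 6),
    error_deg = e,
    next_state_deg = next_state
  )
}

#' Simulate a full session for one participant
#'
#' Runs [simulate_trial()] over a schedule, accumulating session time with a
#' fixed 1.5 s inter-trial interval. Uses the caller's RNG state.
#'
#' @inheritParams simulate_trial
#' @param schedule A [build_schedule()] schedule.
#' @return A tibble (class `reach_sessions`) with one row per trial:
#'   participant metadata, trial metadata, event times, a `samples`
#'   list-column of trajectory matrices, and the latent `state_deg` of the
#'   learner on that trial.
#' @export
simulate_session <- function(params, schedule, visual_delay_frac = 0.25) {
  a <- schedule_attrs(schedule)
  n <- nrow(schedule)
  state <- 0
  t_now <- 0
  samples <- vector("list", n)
  t_start <- t_click <- states <- numeric(n)
  for (i in seq_len(n)) {
    spec <- schedule[i, ]
    tr <- simulate_trial(state, spec, params,
      task = a$task, t_start_ms = t_now,
      visual_delay_frac = visual_delay_frac,
      target_distance_gu = a$target_distance_gu
    )
    samples[[i]] <- tr$samples
    t_start[i] <- tr$t_trial_start_ms
    t_click[i] <- tr$t_click_ms
    states[i] <- state
    state <- tr$next_state_deg
    t_now <- tr$samples[nrow(tr$samples), "t_ms"] + 1500
  }
  out <- tibble(
    participant_id = params$participant_id,
    age_mo = params$age_mo,
    sex = params$sex,
    device = params$device,
    task = a$task,
    trial_index = schedule$trial_index,
    block = schedule$block,
    rotation_deg = schedule$rotation_deg,
    clamp = schedule$clamp,
    clamp_jitter_deg = schedule$clamp_jitter_deg,
    t_trial_start_ms = t_start,
    t_click_ms = t_click,
    state_deg = states,
    samples = samples
  )
  class(out) <- c("reach_sessions", class(out))
  out
}

#' Simulate a synthetic cohort
#'
#' One full session per participant. Ages are drawn uniformly over the
#' configured range (or taken from `ages_mo`); each participant's parameters
#' and session use a private seed derived from `(cohort$seed, index)`, so
#' cohorts are reproducible and participants are independent of ordering.
#'
#' @param cohort A [cohort_config()].
#' @param task `"pushball"` or `"launchball"`.
#' @param visual_delay_frac Passed to [simulate_trial()].
#' @return A `reach_sessions` tibble (all participants stacked).
#' @export
simulate_cohort <- function(cohort = cohort_config(), task = "pushball",
                            visual_delay_frac = 0.25) {
  task <- check_task(task)
  n <- cohort$n_participants
  ages <- cohort$ages_mo %||%
    withr::with_seed(
      derive_seed(cohort$seed, 0L),
      runif(n, cohort$age_range_mo[1], cohort$age_range_mo[2])
    )
  if (length(ages) != n) {
    abort("`ages_mo` must have length `n_participants`.", class = "reachdev_bad_config")
  }
  sessions <- purrr::map(seq_len(n), function(i) {
    id <- sprintf("P%04d", i)
    params <- tryCatch(
      default_age_params(ages[i], cohort,
        seed = derive_seed(cohort$seed, i, 1L),
        participant_id = id
      ),
      error = function(e) {
        abort(paste0("Participant ", id, " (age ", round(ages[i], 1), " mo): ",
          conditionMessage(e)), parent = e)
      }
    )
    schedule <- build_schedule(task, seed = derive_seed(cohort$seed, i, 2L))
    withr::with_seed(
      derive_seed(cohort$seed, i, 3L),
      simulate_session(params, schedule, visual_delay_frac)
    )
  })
  out <- bind_rows(sessions)
  class(out) <- c("reach_sessions", class(out))
  out
}
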