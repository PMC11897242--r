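#' Block structure of a session
#'
#' Trial counts per block for each task. Both tasks share a 90-trial learning
#' block (60-trial ramp to a 30 degree clockwise rotation at 0.5 degrees per
#' trial, then 30 hold trials), a 20-trial error clamp and a 30-trial washout.
#' Launch ball has a longer baseline (40 trials, total 180) because the task
#' is less naturalistic; Push ball has 20 baseline trials (total 160).
#'
#' @param task `"pushball"` or `"launchball"`.
#' @return Named integer vector `c(baseline, learning, clamp, washout)`.
#' @export
task_blocks <- function(task) {
  task <- check_task(task)
  c(
    baseline = if (task == "pushball") 20L else 40L,
    learning = 90L, clamp = 20L, washout = 30L
  )
}

check_task <- function(task) {
  valid <- c("pushball", "launchball")
  if (!is.character(task) || length(task) != 1L || !task %in% valid) {
    abort(paste0(
      "`task` must be one of ", paste0('"', valid, '"', collapse = ", "),
      ", not ", deparse(task), "."
    ), class = "reachdev_bad_task")
  }
  task
}

#' Build the trial schedule of a session
#'
#' Encodes the perturbation program of one game session: a no-rotation
#' baseline, a learning block in which a 30 degree clockwise visuomotor
#' rotation is ramped in at 0.5 degrees per trial over 60 trials and then held
#' for 30 trials, an error-clamp block in which the displayed ball moves
#' nearly straight at the target regardless of the hand (with a small random
#' rotation in \[-2, 2\] degrees per trial), and a no-rotation washout.
#' Clockwise rotations are negative.
#'
#' @param task `"pushball"` (160 trials) or `"launchball"` (180 trials).
#' @param seed Non-negative integer seeding the clamp-jitter draws.
#' @param target_distance_gu Start-to-target distance in game units.
#' @param success_halfwidth_deg Half-width of the success window in degrees.
#' @return A tibble of class `reach_schedule` with one row per trial
#'   (`trial_index`, `block`, `rotation_deg`, `clamp`, `clamp_jitter_deg`) and
#'   attributes `task`, `target_distance_gu`, `success_halfwidth_deg`.
#' @examples
#' sched <- build_schedule("pushball", seed = 1)
#' nrow(sched) # 160
#' @export
build_schedule <- function(task = c("pushball", "launchball"), seed = 0L,
                           target_distance_gu = 24,
                           success_halfwidth_deg = 10) {
  task <- check_task(if (identical(task, c("pushball", "launchball"))) "pushball" else task)
  if (!is_scalar_number(seed) || seed < 0) {
    abort("`seed` must be a single non-negative number.")
  }
  blocks <- task_blocks(task)
  n_ramp <- 60L
  rotation <- c(
    rep(0, blocks[["baseline"]]),
    -0.5 * seq_len(n_ramp),
    rep(-30, blocks[["learning"]] - n_ramp),
    rep(0, blocks[["clamp"]]),
    rep(0, blocks[["washout"]])
  )
  block <- rep(names(blocks), times = blocks)
  n <- sum(blocks)
  clamp <- block == "clamp"
  jitter <- rep(NA_real_, n)
  # quantised to 1e-6 deg so schedules round-trip bit-exactly through JSON
  jitter[clamp] <- round(withr::with_seed(as.integer(seed), runif(sum(clamp), -2, 2)), 6)
  out <- tibble(
    trial_index = seq_len(n),
    block = block,
    rotation_deg = rotation,
    clamp = clamp,
    clamp_jitter_deg = jitter
  )
  structure(
    out,
    task = task,
    target_distance_gu = target_distance_gu,
    success_halfwidth_deg = success_halfwidth_deg,
    class = c("reach_schedule", class(out))
  )
}

schedule_attrs <- function(schedule) {
  list(
    task = attr(schedule, "task"),
    target_distance_gu = attr(schedule, "target_distance_gu"),
    success_halfwidth_deg = attr(schedule, "success_halfwidth_deg")
  )
}

#' Displayed ball angle for a trial
#'
#' During ordinary trials the ball is shown rotated from the hand by the
#' trial's rotation, so the displayed angle is `hand + rotation`. During
#' error-clamp trials the displayed direction is the trial's clamp jitter,
#' independent of the hand.
#'
#' @param hand_angle_deg Hand movement angle(s), degrees, counterclockwise
#'   positive.
#' @param spec One row of a [build_schedule()] schedule (or any list with
#'   `rotation_deg`, `clamp`, `clamp_jitter_deg`).
#' @return Displayed angle(s), degrees.
#' @export
displayed_angle <- function(hand_angle_deg, spec) {
  if (isTRUE(spec$clamp)) {
    rep(spec$clamp_jitter_deg, length(hand_angle_deg))
  } else {
    hand_angle_deg + spec$rotation_deg
  }
}

#' Hit/miss evaluation of a displayed endpoint
#'
#' A trial is a hit when the displayed ball ends within the success window of
#' the target centre (boundary inclusive).
#'
#' @param displayed_final_deg Displayed final angle(s), degrees.
#' @param schedule A [build_schedule()] schedule (supplies the half-width), or
#'   a number giving the half-width directly.
#' @return Logical hit flag(s).
#' @export
evaluate_trial <- function(displayed_final_deg, schedule = 10) {
  hw <- if (is.numeric(schedule)) schedule else attr(schedule, "success_halfwidth_deg")
  abs(displayed_final_deg) <= hw
}

#' Hand-space success zone of a trial
#'
#' The interval of hand angles whose displayed endpoint registers a hit:
#' `[-rotation - hw, -rotation + hw]`. On the 30 degree clockwise hold trials
#' this is 20 to 40 degrees. Clamp trials are rejected: every clamp trial
#' succeeds by construction.
#'
#' @inheritParams displayed_angle
#' @inheritParams evaluate_trial
#' @return Numeric `c(low_deg, high_deg)`.
#' @export
hand_success_zone <- function(spec, schedule = 10) {
  if (isTRUE(spec$clamp)) {
    abort("Clamp trials have no hand-space success zone: every clamp trial is a hit.",
      class = "reachdev_clamp_zone"
    )
  }
  hw <- if (is.numeric(schedule)) schedule else attr(schedule, "success_halfwidth_deg")
  c(-spec$rotation_deg - hw, -spec$rotation_deg + hw)
}

#' Serialize / restore a schedule as JSON
#'
#' Round-trips all fields bit-exactly (rotations are exact halves, jitters are
#' written at full double precision).
#'
#' @param schedule A `reach_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the restored `reach_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  a <- schedule_attrs(schedule)
  obj <- list(
    task = a$task,
    target_distance_gu = a$target_distance_gu,
    success_halfwidth_deg = a$success_halfwidth_deg,
    trials = as.data.frame(schedule)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- as_tibble(obj$trials)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$clamp <- as.logical(trials$clamp)
  if (!"clamp_jitter_deg" %in% names(trials)) trials$clamp_jitter_deg <- NA_real_
  trials$clamp_jitter_deg <- as.numeric(trials$clamp_jitter_deg)
  structure(
    trials,
    task = obj$task,
    target_distance_gu = as.numeric(obj$target_distance_gu),
    success_halfwidth_deg = as.numeric(obj$success_halfwidth_deg),
    class = c("reach_schedule", class(trials))
  )
}
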