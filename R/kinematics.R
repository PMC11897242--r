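#' Movement angle of a sample
#'
#' Signed angle between the start-to-sample chord and the start-to-target
#' ray (straight ahead, 0 degrees), counterclockwise positive and clockwise
#' negative. Vectorised over samples.
#'
#' @param x_gu,y_gu Sample coordinates in game units (start at the origin).
#' @return Signed degrees.
#' @examples
#' movement_angle(-10, 10) # +45
#' movement_angle(10, 10) # -45
#' @export
movement_angle <- function(x_gu, y_gu) {
  if (any(x_gu == 0 & y_gu == 0)) {
    abort("Movement angle is undefined at the start location.",
      class = "reachdev_invalid_trial"
    )
  }
  chord_angle_deg(x_gu, y_gu)
}

# Accepts a samples matrix/data frame with columns t_ms, x_gu, y_gu and
# enforces the trajectory invariants.
as_trajectory <- function(samples) {
  m <- as.matrix(samples[, c("t_ms", "x_gu", "y_gu"), drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) < 2) {
    abort("A trajectory needs at least 2 samples.", class = "reachdev_invalid_trial")
  }
  if (any(diff(m[, "t_ms"]) <= 0)) {
    abort("Trajectory timestamps must be strictly increasing.",
      class = "reachdev_invalid_trial"
    )
  }
  if (m[1, "x_gu"] != 0 || m[1, "y_gu"] != 0) {
    abort("The first trajectory sample must be at the origin.",
      class = "reachdev_invalid_trial"
    )
  }
  m
}

# First sample with nonzero displacement from its predecessor (after
# `after_ms` when given): the movement-onset sample.
onset_time <- function(m, after_ms = -Inf) {
  d <- sqrt(diff(m[, "x_gu"])^2 + diff(m[, "y_gu"])^2)
  idx <- which(d > 0 & m[-1, "t_ms"] >= after_ms)[1] + 1L
  if (is.na(idx)) {
    abort("No movement found in trajectory.", class = "reachdev_invalid_trial")
  }
  unname(m[idx, "t_ms"])
}

ia_index <- function(m, threshold_gu = 1.2, metric = c("euclidean", "path")) {
  metric <- match.arg(metric)
  dist <- if (metric == "euclidean") {
    sqrt(m[, "x_gu"]^2 + m[, "y_gu"]^2)
  } else {
    c(0, cumsum(sqrt(diff(m[, "x_gu"])^2 + diff(m[, "y_gu"])^2)))
  }
  idx <- which(dist >= threshold_gu)[1]
  if (is.na(idx)) {
    abort(sprintf("No sample reaches the %.2f GU initial-angle threshold.", threshold_gu),
      class = "reachdev_invalid_trial"
    )
  }
  idx
}

#' Initial angle and its time
#'
#' Movement angle of the first sample whose distance from the start reaches
#' the threshold (1.2 GU, 5% of the start-target distance), reflecting the
#' feedforward (adapted) part of the movement. `ia_time_ms` is that sample's
#' time relative to movement onset.
#'
#' @param traj Samples matrix/data frame with columns `t_ms`, `x_gu`, `y_gu`.
#' @param threshold_gu Distance threshold in game units.
#' @param metric `"euclidean"` (straight-line distance from start, the
#'   default) or `"path"` (cumulative distance along the path).
#' @return List with `angle_deg`, `ia_time_ms` and the sample `index`.
#' @export
initial_angle <- function(traj, threshold_gu = 1.2,
                          metric = c("euclidean", "path")) {
  m <- as_trajectory(traj)
  idx <- ia_index(m, threshold_gu, metric)
  list(
    angle_deg = movement_angle(m[idx, "x_gu"], m[idx, "y_gu"]),
    ia_time_ms = unname(m[idx, "t_ms"]) - onset_time(m),
    index = idx
  )
}

#' Final angle of a trajectory
#'
#' Movement angle of the start-to-end chord of the hand path: the overall
#' performance measure (adaptation plus any online correction).
#'
#' @inheritParams initial_angle
#' @return Signed degrees.
#' @export
final_angle <- function(traj) {
  m <- as_trajectory(traj)
  last <- m[nrow(m), ]
  if (last[["x_gu"]] == 0 && last[["y_gu"]] == 0) {
    abort("Degenerate trajectory: endpoint at the origin.",
      class = "reachdev_invalid_trial"
    )
  }
  movement_angle(last[["x_gu"]], last[["y_gu"]])
}

#' Launch angle of a trajectory
#'
#' In Launch ball the ball flies along the straight line through the start
#' and end of the hand path, so the launch angle is computed exactly as the
#' final angle.
#'
#' @inheritParams initial_angle
#' @return Signed degrees.
#' @export
launch_angle <- function(traj) final_angle(traj)

#' Compensation angle
#'
#' Final minus initial angle: the within-trial correction attributable to
#' online visual feedback.
#'
#' @param final_deg,initial_deg Signed degrees.
#' @return Signed degrees.
#' @export
compensation_angle <- function(final_deg, initial_deg) final_deg - initial_deg

#' Path length ratio
#'
#' Path length divided by the straight-line distance between first and last
#' sample; 1 for straight movements, larger for curved or zigzag paths.
#'
#' @inheritParams initial_angle
#' @return Unitless ratio, at least 1.
#' @export
path_length_ratio <- function(traj) {
  m <- as_trajectory(traj)
  seg <- sqrt(diff(m[, "x_gu"])^2 + diff(m[, "y_gu"])^2)
  chord <- sqrt(
    (m[nrow(m), "x_gu"] - m[1, "x_gu"])^2 + (m[nrow(m), "y_gu"] - m[1, "y_gu"])^2
  )
  if (chord == 0) {
    abort("Degenerate trajectory: zero first-to-last distance.",
      class = "reachdev_invalid_trial"
    )
  }
  unname(sum(seg) / chord)
}

#' Correction point and normalised correction time
#'
#' The correction window is the initial angle plus/minus `window_deg`. The
#' correction point is the first sample strictly after the initial-angle
#' sample whose movement angle leaves that window; the normalised correction
#' time is its time from movement onset divided by the movement time, i.e.
#' how far into the movement the participant started to correct. `NA` when
#' the path never leaves the window (no correction).
#'
#' @inheritParams initial_angle
#' @param window_deg Half-width of the correction window, degrees.
#' @return List with `correction_index`, `correction_time_ms`,
#'   `norm_correction_time` (all `NA` when no correction occurs).
#' @export
correction_metrics <- function(traj, window_deg = 5, threshold_gu = 1.2,
                               metric = c("euclidean", "path")) {
  m <- as_trajectory(traj)
  ia <- initial_angle(m, threshold_gu, metric)
  t_on <- onset_time(m)
  n <- nrow(m)
  none <- list(
    correction_index = NA_integer_, correction_time_ms = NA_real_,
    norm_correction_time = NA_real_
  )
  if (ia$index >= n) {
    return(none)
  }
  idx <- seq(ia$index + 1L, n)
  ang <- chord_angle_deg(m[idx, "x_gu"], m[idx, "y_gu"])
  out <- which(abs(ang - ia$angle_deg) > window_deg)[1]
  if (is.na(out)) {
    return(none)
  }
  ci <- idx[out]
  movement <- unname(m[n, "t_ms"]) - t_on
  t_corr <- unname(m[ci, "t_ms"])
  list(
    correction_index = ci,
    correction_time_ms = t_corr - t_on,
    norm_correction_time = (t_corr - t_on) / movement
  )
}

#' Angle spread of a trajectory
#'
#' Difference between the maximum and minimum movement angle over the
#' samples from the initial-angle sample to the end of the path: how much of
#' the game space the trajectory swept.
#'
#' @inheritParams correction_metrics
#' @return Degrees, at least 0.
#' @export
angle_spread <- function(traj, threshold_gu = 1.2,
                         metric = c("euclidean", "path")) {
  m <- as_trajectory(traj)
  ia <- initial_angle(m, threshold_gu, metric)
  idx <- seq(ia$index, nrow(m))
  ang <- chord_angle_deg(m[idx, "x_gu"], m[idx, "y_gu"])
  max(ang) - min(ang)
}

#' Reaction, stationary and movement time
#'
#' Reaction time is trial start to ball click; stationary time is click to
#' movement onset (the first sample with nonzero displacement after the
#' click); movement time is onset to the last sample. All `NA` when event
#' times are missing (the trial is retained for spatial measures).
#'
#' @inheritParams initial_angle
#' @param t_trial_start_ms,t_click_ms Event times, same clock as the samples.
#' @return List with `reaction_ms`, `stationary_ms`, `movement_ms`.
#' @export
timing_measures <- function(traj, t_trial_start_ms, t_click_ms) {
  if (is.na(t_trial_start_ms) || is.na(t_click_ms)) {
    return(list(reaction_ms = NA_real_, stationary_ms = NA_real_, movement_ms = NA_real_))
  }
  m <- as_trajectory(traj)
  t_on <- onset_time(m, after_ms = t_click_ms)
  list(
    reaction_ms = t_click_ms - t_trial_start_ms,
    stationary_ms = t_on - t_click_ms,
    movement_ms = unname(m[nrow(m), "t_ms"]) - t_on
  )
}

measure_columns <- function() {
  c(
    "initial_angle_deg", "ia_time_ms", "final_angle_deg", "launch_angle_deg",
    "compensation_angle_deg", "path_length_ratio", "norm_correction_time",
    "angle_spread_deg", "reaction_ms", "stationary_ms", "movement_ms"
  )
}

# All per-trial scalars for one trajectory; invalid trials yield NA measures
# plus a reason instead of an error.
compute_measures_row <- function(samples, t_trial_start_ms, t_click_ms,
                                 rotation_deg, clamp, clamp_jitter_deg, task,
                                 success_halfwidth_deg = 10, threshold_gu = 1.2,
                                 window_deg = 5, metric = "euclidean") {
  out <- as.list(setNames(rep(NA_real_, length(measure_columns())), measure_columns()))
  out$hit <- NA
  out$valid <- FALSE
  out$invalid_reason <- NA_character_
  res <- tryCatch(
    {
      m <- as_trajectory(samples)
      ia <- initial_angle(m, threshold_gu, metric)
      fa <- final_angle(m)
      out$initial_angle_deg <- ia$angle_deg
      out$ia_time_ms <- ia$ia_time_ms
      out$final_angle_deg <- fa
      out$launch_angle_deg <- fa
      out$compensation_angle_deg <- compensation_angle(fa, ia$angle_deg)
      out$path_length_ratio <- path_length_ratio(m)
      out$angle_spread_deg <- angle_spread(m, threshold_gu, metric)
      if (task == "pushball") {
        out$norm_correction_time <-
          correction_metrics(m, window_deg, threshold_gu, metric)$norm_correction_time
      }
      tm <- timing_measures(m, t_trial_start_ms, t_click_ms)
      out$reaction_ms <- tm$reaction_ms
      out$stationary_ms <- tm$stationary_ms
      out$movement_ms <- tm$movement_ms
      disp <- if (isTRUE(clamp)) clamp_jitter_deg else fa + rotation_deg
      out$hit <- abs(disp) <= success_halfwidth_deg
      out$valid <- TRUE
      out
    },
    reachdev_invalid_trial = function(e) {
      out$invalid_reason <- conditionMessage(e)
      out
    }
  )
  res
}

#' Per-trial measures for a set of sessions
#'
#' Computes every per-trial measure (initial, final, launch and compensation
#' angles, path-length ratio, normalised correction time, angle spread,
#' reaction/stationary/movement times, hit flag) for each trial of a
#' `reach_sessions` table. Trials whose trajectory never reaches the
#' initial-angle threshold, or is otherwise degenerate, are flagged invalid
#' with a reason and carry `NA` measures; Launch ball trials carry `NA`
#' normalised correction time by design (no online feedback exists to
#' correct with).
#'
#' @param sessions A `reach_sessions` tibble ([simulate_cohort()] or
#'   [read_sessions()]).
#' @param success_halfwidth_deg Success window half-width, degrees.
#' @param threshold_gu Initial-angle distance threshold, game units.
#' @param window_deg Correction-window half-width, degrees.
#' @param metric Initial-angle threshold metric, `"euclidean"` or `"path"`.
#' @return A tibble with one row per trial: the session metadata columns plus
#'   all measures, `hit`, `valid` and `invalid_reason`.
#' @export
extract_measures <- function(sessions, success_halfwidth_deg = 10,
                             threshold_gu = 1.2, window_deg = 5,
                             metric = c("euclidean", "path")) {
  metric <- match.arg(metric)
  n <- nrow(sessions)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- compute_measures_row(
      sessions$samples[[i]], sessions$t_trial_start_ms[i], sessions$t_click_ms[i],
      sessions$rotation_deg[i], sessions$clamp[i], sessions$clamp_jitter_deg[i],
      sessions$task[i], success_halfwidth_deg, threshold_gu, window_deg, metric
    )
  }
  meta <- dplyr::select(as_tibble(sessions), -dplyr::any_of(c(
    "samples", "t_trial_start_ms", "t_click_ms", "state_deg"
  )))
  vals <- purrr::list_transpose(rows)
  measures <- as_tibble(lapply(vals, unlist))
  dplyr::bind_cols(meta, measures)
}
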