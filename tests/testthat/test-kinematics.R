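# path with a prescribed chord-angle profile: sample i sits at radius r[i]
# along chord angle theta[i] (degrees, CCW positive)
path_from_angles <- function(theta, r, t = (seq_along(r) - 1) * 10) {
  th <- theta * pi / 180
  cbind(t_ms = t, x_gu = -r * sin(th), y_gu = r * cos(th))
}

test_that("movement angle is signed CCW-positive relative to the target line", {
  expect_equal(movement_angle(0, 10), 0)
  expect_equal(movement_angle(-10, 10), 45)
  expect_equal(movement_angle(10, 10), -45)
  expect_equal(movement_angle(-6, 24), atan2(6, 24) * 180 / pi, tolerance = 1e-12)
  expect_equal(round(movement_angle(6, 24), 2), -14.04)
  expect_error(movement_angle(0, 0), class = "reachdev_invalid_trial")
})

test_that("initial angle picks the first sample past the 1.2 GU threshold", {
  straight <- path_from_angles(rep(30, 10), seq(0, 4.5, by = 0.5))
  ia <- initial_angle(straight)
  expect_equal(ia$angle_deg, 30, tolerance = 1e-9)

  # heads at 0 deg for its first 2 GU, then turns to 40: threshold is crossed
  # on the first leg
  turning <- rbind(
    c(0, 0, 0), c(10, 0, 1), c(20, 0, 2),
    c(30, -2 * sin(40 * pi / 180), 2 + 2 * cos(40 * pi / 180))
  )
  colnames(turning) <- c("t_ms", "x_gu", "y_gu")
  expect_equal(initial_angle(turning)$angle_deg, 0)

  below <- path_from_angles(rep(5, 5), seq(0, 1.0, length.out = 5))
  expect_error(initial_angle(below), class = "reachdev_invalid_trial")
})

test_that("final and launch angle are the start-to-end chord angle", {
  curved <- path_from_angles(c(0, 20, 28, 10), c(0, 1, 3, 6))
  m <- curved
  m[nrow(m), c("x_gu", "y_gu")] <- c(-6, 24)
  expect_equal(final_angle(m), atan2(6, 24) * 180 / pi, tolerance = 1e-12)
  expect_equal(launch_angle(m), final_angle(m))
  zig <- path_from_angles(c(0, -25, 40, 30), c(0, 2, 5, 24 / cos(30 * pi / 180)))
  expect_equal(final_angle(zig), 30, tolerance = 1e-9)
  expect_equal(compensation_angle(30, 12), 18)
  expect_equal(compensation_angle(-5, 10), -15)
})

test_that("path length ratio is 1 for straight paths and sqrt(2) for a right angle", {
  straight <- path_from_angles(rep(12, 8), 0:7)
  expect_equal(path_length_ratio(straight), 1, tolerance = 1e-12)
  elbow <- cbind(t_ms = c(0, 10, 20), x_gu = c(0, 0, -2), y_gu = c(0, 2, 2))
  expect_equal(path_length_ratio(elbow), sqrt(2), tolerance = 1e-12)
})

test_that("correction point is the first exit from the IA +/- 5 deg window", {
  const <- path_from_angles(rep(10, 12), 0:11)
  expect_true(is.na(correction_metrics(const)$norm_correction_time))

  # IA = 10 deg at sample 3; chord angle jumps to 16 deg at sample 7;
  # onset at sample 2 (t = 10), last sample t = 110: nct = (60-10)/100
  theta <- c(10, 10, 10, 10, 11, 12, 16, 16, 16, 16, 16, 16)
  fix <- path_from_angles(theta, 0:11)
  cm <- correction_metrics(fix)
  expect_equal(cm$correction_index, 7L)
  expect_equal(cm$norm_correction_time, 0.5, tolerance = 1e-12)
})

test_that("angle spread spans the chord angles from the IA sample onward", {
  theta <- c(0, 10, 10, 35, 20, 15)
  fix <- path_from_angles(theta, c(0, 1.5, 2.5, 4, 6, 8))
  expect_equal(angle_spread(fix), 25, tolerance = 1e-9)
  straight <- path_from_angles(rep(7, 6), seq(0, 5))
  expect_equal(angle_spread(straight), 0, tolerance = 1e-12)
})

test_that("timing measures are the event-time differences", {
  m <- cbind(t_ms = c(900, 950, 1400, 2150), x_gu = c(0, 0, -1, -2), y_gu = c(0, 0.5, 12, 24))
  tm <- timing_measures(m, t_trial_start_ms = 0, t_click_ms = 800)
  expect_equal(tm$reaction_ms, 800)
  expect_equal(tm$stationary_ms, 150)
  expect_equal(tm$movement_ms, 1200)
  # movement beginning exactly at the click: zero stationary time
  m2 <- cbind(t_ms = c(700, 800, 1500), x_gu = c(0, 0.2, 1), y_gu = c(0, 1, 10))
  expect_equal(timing_measures(m2, 0, 800)$stationary_ms, 0)
  expect_true(is.na(timing_measures(m, NA, 800)$movement_ms))
})

test_that("rotating a trajectory shifts the angles and preserves shape measures", {
  withr::with_seed(5, {
    for (delta in c(-30, -15, 15, 30)) {
      m <- random_trajectory(20)
      r <- sqrt(m[, 2]^2 + m[, 3]^2)
      th <- ifelse(r == 0, 0, atan2(-m[, 2], m[, 3]) * 180 / pi)
      rot <- path_from_angles(th + delta, r, t = m[, 1])
      expect_equal(initial_angle(rot)$angle_deg,
        initial_angle(m)$angle_deg + delta,
        tolerance = 1e-9
      )
      expect_equal(final_angle(rot), final_angle(m) + delta, tolerance = 1e-9)
      expect_equal(path_length_ratio(rot), path_length_ratio(m), tolerance = 1e-9)
      expect_equal(angle_spread(rot), angle_spread(m), tolerance = 1e-9)
    }
  })
})

test_that("angle spread bounds the compensation angle on random paths", {
  withr::with_seed(11, {
    for (i in 1:100) {
      m <- random_trajectory()
      ia <- initial_angle(m)$angle_deg
      fa <- final_angle(m)
      expect_gte(angle_spread(m) + 1e-12, abs(compensation_angle(fa, ia)))
    }
  })
})

test_that("invalid trials are flagged with a reason, not dropped silently", {
  short <- path_from_angles(rep(5, 4), c(0, 0.3, 0.6, 0.9))
  sessions <- tibble::tibble(
    participant_id = "P1", age_mo = 100, sex = "F", device = "mouse",
    task = "pushball", trial_index = 1L, block = "baseline",
    rotation_deg = 0, clamp = FALSE, clamp_jitter_deg = NA_real_,
    t_trial_start_ms = 0, t_click_ms = NA_real_,
    samples = list(short)
  )
  m <- extract_measures(sessions)
  expect_false(m$valid[1])
  expect_match(m$invalid_reason[1], "threshold")
  expect_true(is.na(m$initial_angle_deg[1]))
})
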