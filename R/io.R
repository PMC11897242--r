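session_fields <- function() {
  c(
    "participant_id", "age_mo", "sex", "device", "task", "trial_index",
    "block", "rotation_deg", "clamp", "clamp_jitter_deg", "events", "samples"
  )
}

#' Write sessions as JSON lines
#'
#' One JSON object per trial: participant metadata, trial metadata, event
#' times and the raw trajectory samples. Numeric fields are carried with at
#' most 6 fractional digits (the simulator already quantises times and
#' positions to that precision), so write followed by read is lossless.
#' Paths ending in `.gz` are written gzip-compressed.
#'
#' @param sessions A `reach_sessions` tibble.
#' @param path Output file path (`.jsonl` or `.jsonl.gz`).
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  lines <- purrr::map_chr(seq_len(nrow(sessions)), function(i) {
    row <- sessions[i, ]
    obj <- list(
      participant_id = row$participant_id,
      age_mo = round(row$age_mo, 6),
      sex = row$sex,
      device = row$device,
      task = row$task,
      trial_index = row$trial_index,
      block = row$block,
      rotation_deg = row$rotation_deg,
      clamp = row$clamp,
      clamp_jitter_deg = row$clamp_jitter_deg,
      events = list(
        t_trial_start_ms = row$t_trial_start_ms,
        t_click_ms = row$t_click_ms
      ),
      samples = unname(row$samples[[1]])
    )
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  })
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

check_session_record <- function(rec, line_no) {
  req <- setdiff(session_fields(), "clamp_jitter_deg")
  missing <- setdiff(req, names(rec))
  if (length(missing)) {
    abort(sprintf(
      "Line %d: missing field(s) %s.", line_no,
      paste(missing, collapse = ", ")
    ), class = "reachdev_io_error")
  }
  s <- rec$samples
  if (is.null(dim(s))) s <- matrix(s, ncol = 3, byrow = FALSE)
  if (ncol(s) != 3 || nrow(s) < 2) {
    abort(sprintf("Line %d (trial %s): samples must be an n x 3 array with n >= 2.",
      line_no, rec$trial_index
    ), class = "reachdev_io_error")
  }
  colnames(s) <- c("t_ms", "x_gu", "y_gu")
  if (any(diff(s[, "t_ms"]) <= 0)) {
    abort(sprintf(
      "Line %d (participant %s, trial %s): non-monotone sample timestamps.",
      line_no, rec$participant_id, rec$trial_index
    ), class = "reachdev_io_error")
  }
  if (s[1, "x_gu"] != 0 || s[1, "y_gu"] != 0) {
    abort(sprintf(
      "Line %d (participant %s, trial %s): first sample not at the origin.",
      line_no, rec$participant_id, rec$trial_index
    ), class = "reachdev_io_error")
  }
  rec$samples <- s
  rec
}

#' Read sessions from JSON lines
#'
#' Validates every record: required fields, strictly increasing timestamps,
#' first sample at the origin. Malformed lines are rejected with their line
#' number; an empty file yields an empty table with a warning.
#'
#' @param path A `.jsonl` (optionally `.gz`) file written by
#'   [write_sessions()].
#' @return A `reach_sessions` tibble.
#' @export
read_sessions <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warn("Empty session file; returning an empty session table.")
    return(structure(tibble(), class = c("reach_sessions", class(tibble()))))
  }
  recs <- purrr::map(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) {
        abort(sprintf("Line %d: malformed JSON (%s).", i, conditionMessage(e)),
          class = "reachdev_io_error"
        )
      }
    )
    check_session_record(rec, i)
  })
  out <- tibble(
    participant_id = purrr::map_chr(recs, "participant_id"),
    age_mo = purrr::map_dbl(recs, "age_mo"),
    sex = purrr::map_chr(recs, "sex"),
    device = purrr::map_chr(recs, "device"),
    task = purrr::map_chr(recs, "task"),
    trial_index = purrr::map_int(recs, ~ as.integer(.x$trial_index)),
    block = purrr::map_chr(recs, "block"),
    rotation_deg = purrr::map_dbl(recs, "rotation_deg"),
    clamp = purrr::map_lgl(recs, "clamp"),
    clamp_jitter_deg = purrr::map_dbl(recs, ~ {
      j <- .x$clamp_jitter_deg
      if (is.null(j)) NA_real_ else as.numeric(j)
    }),
    t_trial_start_ms = purrr::map_dbl(recs, ~ .x$events$t_trial_start_ms),
    t_click_ms = purrr::map_dbl(recs, ~ .x$events$t_click_ms),
    samples = purrr::map(recs, "samples")
  )
  class(out) <- c("reach_sessions", class(out))
  out
}

#' Quality-control policy
#'
#' Mirrors the study's data review: sessions longer than 2 hours, sessions
#' with inadequate input-device sampling, and participants who did not
#' finish the whole experiment are excluded.
#'
#' @param max_session_minutes Maximum total game duration.
#' @param min_median_polling_hz Minimum median sampling rate during
#'   movement (stationary periods produce no polls).
#' @param completion_required Exclude participants lacking the full trial
#'   count for their task.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(max_session_minutes = 120, min_median_polling_hz = 20,
                      completion_required = TRUE) {
  if (max_session_minutes <= 0 || min_median_polling_hz <= 0) {
    abort("QC thresholds must be positive.", class = "reachdev_bad_config")
  }
  structure(
    list(
      max_session_minutes = max_session_minutes,
      min_median_polling_hz = min_median_polling_hz,
      completion_required = completion_required
    ),
    class = "qc_policy"
  )
}

#' Apply quality control to sessions
#'
#' @param sessions A `reach_sessions` tibble.
#' @param policy A [qc_policy()].
#' @return List with `sessions` (kept trials) and `report` (one row per
#'   exclusion: participant, rule, observed value, threshold).
#' @export
apply_qc <- function(sessions, policy = qc_policy()) {
  per <- sessions |>
    group_by(.data$participant_id, .data$task) |>
    summarise(
      n_trials = n(),
      duration_min = (max(purrr::map_dbl(.data$samples, ~ max(.x[, "t_ms"]))) -
        min(.data$t_trial_start_ms)) / 60000,
      median_polling_hz = 1000 / median(unlist(purrr::map(
        .data$samples, ~ diff(.x[, "t_ms"])
      ))),
      .groups = "drop"
    ) |>
    mutate(expected_trials = purrr::map_int(.data$task, ~ sum(task_blocks(.x))))
  report <- bind_rows(
    per |> filter(.data$duration_min > policy$max_session_minutes) |>
      mutate(rule = "max_session_minutes", value = .data$duration_min,
        threshold = policy$max_session_minutes),
    per |> filter(.data$median_polling_hz < policy$min_median_polling_hz) |>
      mutate(rule = "min_median_polling_hz", value = .data$median_polling_hz,
        threshold = policy$min_median_polling_hz),
    if (policy$completion_required) {
      per |> filter(.data$n_trials != .data$expected_trials) |>
        mutate(rule = "completion_required", value = as.numeric(.data$n_trials),
          threshold = as.numeric(.data$expected_trials))
    }
  ) |>
    select("participant_id", "rule", "value", "threshold")
  kept <- sessions |> filter(!.data$participant_id %in% report$participant_id)
  class(kept) <- class(sessions)
  list(sessions = kept, report = report)
}
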