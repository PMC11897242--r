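#' Epoch windows of a session
#'
#' The analysis epochs: the last 10 baseline trials, the last 10 learning
#' trials (`end_learning`), the first and last 3 error-clamp trials
#' (`early_clamp`, `end_clamp`), and the first 3 and last 10 washout trials
#' (`early_washout`, `end_washout`). Fewer trials are averaged where rapid
#' changes are expected.
#'
#' @param task `"pushball"` or `"launchball"` (sets the baseline length).
#' @return Tibble with columns `epoch` and `trial_index`.
#' @export
epoch_windows <- function(task = "pushball") {
  blocks <- task_blocks(task)
  ends <- cumsum(blocks)
  starts <- ends - blocks + 1L
  win <- function(block, take, from_end) {
    idx <- starts[[block]]:ends[[block]]
    if (from_end) tail(idx, take) else head(idx, take)
  }
  tibble(
    epoch = rep(
      c(
        "baseline", "end_learning", "early_clamp", "end_clamp",
        "early_washout", "end_washout"
      ),
      times = c(10, 10, 3, 3, 3, 10)
    ),
    trial_index = c(
      win("baseline", 10, TRUE), win("learning", 10, TRUE),
      win("clamp", 3, FALSE), win("clamp", 3, TRUE),
      win("washout", 3, FALSE), win("washout", 10, TRUE)
    )
  )
}

#' Epoch summaries of per-trial measures
#'
#' Per participant, epoch and measure: mean, standard deviation (n - 1
#' denominator) and the number of valid trials. Invalid trials are dropped
#' from the mean with `n_trials` decremented; an epoch with zero valid
#' trials is absent from the result.
#'
#' @param measures Output of [extract_measures()].
#' @param measure_cols Character vector of measure columns to summarise.
#' @return Tidy tibble: `participant_id`, `age_mo`, `epoch`, `measure`,
#'   `mean`, `sd`, `n_trials`.
#' @export
extract_epochs <- function(measures, measure_cols = c(
                             "initial_angle_deg", "final_angle_deg",
                             "compensation_angle_deg"
                           )) {
  missing_cols <- setdiff(c("participant_id", "trial_index", measure_cols), names(measures))
  if (length(missing_cols)) {
    abort(paste0("`measures` lacks columns: ", paste(missing_cols, collapse = ", ")),
      class = "reachdev_bad_columns"
    )
  }
  if (!"age_mo" %in% names(measures)) measures$age_mo <- NA_real_
  windows <- epoch_windows(measures$task[1] %||% "pushball")
  long <- measures |>
    dplyr::inner_join(windows, by = "trial_index") |>
    filter(.data$valid) |>
    tidyr::pivot_longer(all_of(measure_cols), names_to = "measure", values_to = "value") |>
    filter(!is.na(.data$value))
  long |>
    group_by(.data$participant_id, .data$age_mo, .data$epoch, .data$measure) |>
    summarise(
      mean = mean(.data$value), sd = sd(.data$value), n_trials = n(),
      .groups = "drop"
    ) |>
    mutate(epoch = factor(.data$epoch, levels = unique(windows$epoch))) |>
    arrange(.data$participant_id, .data$epoch, .data$measure)
}

#' Per-participant variability of initial and final angle
#'
#' Standard deviations of the initial and final angle over the baseline and
#' end-of-learning epochs: the precision counterpart of the accuracy
#' (mean-based) measures, used for the variability growth curves.
#'
#' @inheritParams extract_epochs
#' @return Tibble: `participant_id`, `age_mo`, `epoch`, `measure`, `sd`,
#'   `n_trials`.
#' @export
variability_summary <- function(measures) {
  extract_epochs(measures, measure_cols = c("initial_angle_deg", "final_angle_deg")) |>
    filter(.data$epoch %in% c("baseline", "end_learning")) |>
    select("participant_id", "age_mo", "epoch", "measure", "sd", "n_trials")
}
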