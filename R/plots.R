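#' Trial-by-trial adaptation course
#'
#' Group-mean initial and final angle by trial, the standard view of the
#' session: adaptation ramps up through learning, persists into the error
#' clamp (the aftereffect) and decays through washout.
#'
#' @param measures Output of [extract_measures()].
#' @return A ggplot object.
#' @export
plot_adaptation_course <- function(measures) {
  d <- measures |>
    filter(.data$valid) |>
    group_by(.data$trial_index, .data$block) |>
    summarise(
      initial = mean(.data$initial_angle_deg, na.rm = TRUE),
      final = mean(.data$final_angle_deg, na.rm = TRUE),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(c("initial", "final"),
      names_to = "measure", values_to = "angle_deg"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$trial_index, y = .data$angle_deg, colour = .data$measure
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Trial", y = "Angle (deg)", colour = NULL,
      title = "Group mean initial and final angle by trial"
    ) +
    ggplot2::theme_minimal()
}

#' Epoch summary bar plot
#'
#' Mean measure per epoch across participants, one panel per measure.
#'
#' @param epochs Output of [extract_epochs()].
#' @return A ggplot object.
#' @export
plot_epoch_summary <- function(epochs) {
  d <- epochs |>
    group_by(.data$epoch, .data$measure) |>
    summarise(value = mean(.data$mean), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Mean over participants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
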