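new_devcurve_fit <- function(model, a, b, ci_a, ci_b, adj_r2, n, data, fit) {
  structure(
    list(
      model = model, a = a, b = b, ci_a = ci_a, ci_b = ci_b,
      adj_r2 = adj_r2, n = n, data = data, fit = fit
    ),
    class = "devcurve_fit"
  )
}

curve_xy <- function(data, y, age) {
  d <- tibble(
    age_mo = as.numeric(dplyr::pull(data, {{ age }})),
    y = as.numeric(dplyr::pull(data, {{ y }}))
  )
  d <- d[is.finite(d$age_mo) & is.finite(d$y), ]
  if (nrow(d) < 3) {
    abort("Curve fits need at least 3 complete observations.",
      class = "reachdev_fit_error"
    )
  }
  if (any(d$age_mo <= 0)) {
    abort("Ages must be positive for developmental curve fits.",
      class = "reachdev_fit_error"
    )
  }
  d
}

#' Developmental curve fits
#'
#' Two-parameter models of a measure against age in months, as used for the
#' maturation of adaptation and performance:
#' * inverse: `y = a + b / age_mo` (plateauing at `a` in adulthood);
#' * logarithmic: `y = a * log(age_mo) + b`;
#' * exponential: `y = a * exp(b * age_mo)` (used for standard deviations
#'   and the compensation angle).
#'
#' The inverse and logarithmic models are linear in a transformed predictor
#' and fitted by least squares; the exponential model is fitted by nonlinear
#' least squares with a deterministic log-linear start. Confidence intervals
#' are 95% Wald intervals. Adults should be excluded by the caller before
#' fitting.
#'
#' @param data A data frame.
#' @param y Measure column (tidy-eval).
#' @param age Age column in months (tidy-eval), default `age_mo`.
#' @return A `devcurve_fit` object with fields `model`, `a`, `b`, `ci_a`,
#'   `ci_b`, `adj_r2`, `n`; supports [tidy()], [glance()], [predict()] and
#'   [autoplot()].
#' @examples
#' d <- tibble::tibble(age_mo = 40:200, y = 25 - 700 / age_mo)
#' fit_inverse(d, y)
#' @export
fit_inverse <- function(data, y, age = age_mo) {
  d <- curve_xy(data, {{ y }}, {{ age }})
  m <- lm(y ~ I(1 / age_mo), data = d)
  ci <- confint(m)
  new_devcurve_fit(
    "inverse",
    a = unname(coef(m)[1]), b = unname(coef(m)[2]),
    ci_a = unname(ci[1, ]), ci_b = unname(ci[2, ]),
    adj_r2 = summary(m)$adj.r.squared, n = nrow(d), data = d, fit = m
  )
}

#' @rdname fit_inverse
#' @export
fit_log <- function(data, y, age = age_mo) {
  d <- curve_xy(data, {{ y }}, {{ age }})
  m <- lm(y ~ log(age_mo), data = d)
  ci <- confint(m)
  new_devcurve_fit(
    "logarithmic",
    a = unname(coef(m)[2]), b = unname(coef(m)[1]),
    ci_a = unname(ci[2, ]), ci_b = unname(ci[1, ]),
    adj_r2 = summary(m)$adj.r.squared, n = nrow(d), data = d, fit = m
  )
}

#' @rdname fit_inverse
#' @export
fit_exponential <- function(data, y, age = age_mo) {
  d <- curve_xy(data, {{ y }}, {{ age }})
  # deterministic start: slope of log|y| on age, amplitude from the youngest
  sgn <- sign(mean(d$y))
  if (sgn == 0) sgn <- 1
  ly <- log(pmax(abs(d$y), 1e-8))
  start_fit <- lm(ly ~ age_mo, data = d)
  start <- list(a = sgn * exp(unname(coef(start_fit)[1])), b = unname(coef(start_fit)[2]))
  m <- tryCatch(
    nls(y ~ a * exp(b * age_mo),
      data = d, start = start,
      control = stats::nls.control(maxiter = 200, scaleOffset = 1)
    ),
    error = function(e) {
      abort(paste0("Exponential fit did not converge: ", conditionMessage(e)),
        class = "reachdev_fit_error", parent = e
      )
    }
  )
  cf <- coef(m)
  se <- sqrt(diag(vcov(m)))
  z <- stats::qt(0.975, df = nrow(d) - 2)
  rss <- sum(stats::resid(m)^2)
  tss <- sum((d$y - mean(d$y))^2)
  adj_r2 <- 1 - (rss / (nrow(d) - 2)) / (tss / (nrow(d) - 1))
  new_devcurve_fit(
    "exponential",
    a = unname(cf["a"]), b = unname(cf["b"]),
    ci_a = unname(cf["a"] + c(-1, 1) * z * se["a"]),
    ci_b = unname(cf["b"] + c(-1, 1) * z * se["b"]),
    adj_r2 = adj_r2, n = nrow(d), data = d, fit = m
  )
}

#' Select the best developmental model
#'
#' Returns the candidate fit with the highest adjusted R-squared; exact ties
#' are broken toward the inverse model (the default, biologically-plateauing
#' choice), then alphabetically for determinism.
#'
#' @param fits A list of `devcurve_fit` objects on the same data.
#' @return The selected `devcurve_fit`, with an `adj_r2_table` attribute
#'   recording all candidates.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "devcurve_fit")) fits <- list(fits)
  if (length(fits) < 1) abort("Need at least one fit.", class = "reachdev_fit_error")
  tab <- tibble(
    model = purrr::map_chr(fits, "model"),
    adj_r2 = purrr::map_dbl(fits, "adj_r2")
  )
  pref <- ifelse(tab$model == "inverse", 0L, 1L)
  best <- order(-tab$adj_r2, pref, tab$model)[1]
  out <- fits[[best]]
  attr(out, "adj_r2_table") <- tab
  out
}

#' @export
predict.devcurve_fit <- function(object, newdata = NULL, age_mo = NULL, ...) {
  age <- age_mo %||% (if (!is.null(newdata)) newdata$age_mo else object$data$age_mo)
  switch(object$model,
    inverse = object$a + object$b / age,
    logarithmic = object$a * log(age) + object$b,
    exponential = object$a * exp(object$b * age)
  )
}

#' @export
print.devcurve_fit <- function(x, ...) {
  cat(sprintf(
    "<devcurve_fit> %s model: a = %.4g (%.4g, %.4g), b = %.4g (%.4g, %.4g)\n",
    x$model, x$a, x$ci_a[1], x$ci_a[2], x$b, x$ci_b[1], x$ci_b[2]
  ))
  cat(sprintf("  adjusted R^2 = %.3f, n = %d\n", x$adj_r2, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.devcurve_fit <- function(x, ...) {
  tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    conf.low = c(x$ci_a[1], x$ci_b[1]),
    conf.high = c(x$ci_a[2], x$ci_b[2])
  )
}

#' @exportS3Method generics::glance
glance.devcurve_fit <- function(x, ...) {
  tibble(model = x$model, adj.r.squared = x$adj_r2, nobs = x$n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.devcurve_fit <- function(object, ...) {
  grid <- tibble(age_mo = seq(min(object$data$age_mo), max(object$data$age_mo),
    length.out = 200
  ))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age_mo, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "grey30", linewidth = 1) +
    ggplot2::labs(
      x = "Age (months)", y = "Measure",
      title = sprintf("%s fit: a = %.2f, b = %.3g", object$model, object$a, object$b)
    ) +
    ggplot2::theme_minimal()
}
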