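# Spline design for one LMS parameter curve. df counts smoothing degrees of
# freedom beyond the constant: df = 0 is a flat (age-constant) parameter,
# df >= 1 adds a natural cubic spline of that dimension.
lms_basis <- function(age, df) {
  if (df <= 0) {
    list(
      ncoef = 1L,
      X = matrix(1, length(age), 1L),
      eval = function(a) matrix(1, length(a), 1L)
    )
  } else {
    B <- splines::ns(age, df = df)
    list(
      ncoef = df + 1L,
      X = cbind(1, B),
      eval = function(a) cbind(1, predict(B, a))
    )
  }
}

bccg_z <- function(y, mu, sigma, lambda) {
  ifelse(abs(lambda) < 1e-4,
    log(y / mu) / sigma,
    ((y / mu)^lambda - 1) / (lambda * sigma)
  )
}

#' Fit age-conditional LMS reference curves
#'
#' Estimates smooth age-varying distribution parameters for a measure by
#' maximum likelihood, for use as percentile reference ("growth") curves.
#' Two families are supported:
#' * `NO`: y ~ Normal(mu(age), sigma(age)^2), with the Box-Cox power fixed
#'   at lambda = 1 (0 df);
#' * `BCCG` (Box-Cox Cole-Green): z = ((y/mu)^lambda - 1) / (lambda sigma)
#'   (log form at lambda = 0) standard normal, modelling median, coefficient
#'   of variation and skewness; requires strictly positive responses.
#'
#' Each parameter depends on age through a natural cubic spline with the
#' stated degrees of freedom (0 = constant). If a BCCG fit is requested but
#' the response contains zeros or negative values, the fit falls back to the
#' `NO` family with a warning. Initialisation is deterministic (lambda = 1,
#' mu from a smooth mean fit, sigma from residual spread), so fits are
#' seed-free.
#'
#' @param data A data frame.
#' @param y Response column (tidy-eval).
#' @param age Age column in months (tidy-eval), default `age_mo`.
#' @param family `"NO"` or `"BCCG"`.
#' @param df Named smoothing df per parameter, e.g.
#'   `c(mu = 3, sigma = 3, lambda = 1)` (lambda entry ignored for `NO`).
#' @return An `lms_fit` object: family, per-parameter coefficient vectors and
#'   basis evaluators, `logLik`, `aic` (`-2 logLik + 2 * total df`), total
#'   `df`, `n`, the fitted age range and the data. Supports [tidy()],
#'   [glance()], [predict()] (via [lms_params()]) and [autoplot()].
#' @export
fit_lms <- function(data, y, age = age_mo, family = c("BCCG", "NO"),
                    df = c(mu = 3, sigma = 3, lambda = 1)) {
  family <- match.arg(family)
  d <- tibble(
    age_mo = as.numeric(dplyr::pull(data, {{ age }})),
    y = as.numeric(dplyr::pull(data, {{ y }}))
  )
  d <- d[is.finite(d$age_mo) & is.finite(d$y), ]
  if (nrow(d) < 20) {
    abort("LMS fits need at least 20 observations.", class = "reachdev_fit_error")
  }
  if (family == "BCCG" && any(d$y <= 0)) {
    warn(paste(
      "Response contains zero or negative values;",
      "falling back from BCCG to the NO family."
    ), class = "reachdev_lms_fallback")
    family <- "NO"
  }
  df <- c(
    mu = unname(df["mu"] %||% 3), sigma = unname(df["sigma"] %||% 3),
    lambda = unname(df["lambda"] %||% 1)
  )
  df[is.na(df)] <- c(mu = 3, sigma = 3, lambda = 1)[is.na(df)]

  b_mu <- lms_basis(d$age_mo, df[["mu"]])
  b_sg <- lms_basis(d$age_mo, df[["sigma"]])
  b_lm <- if (family == "BCCG") lms_basis(d$age_mo, df[["lambda"]]) else NULL

  n_mu <- b_mu$ncoef
  n_sg <- b_sg$ncoef
  n_lm <- if (family == "BCCG") b_lm$ncoef else 0L
  split_par <- function(par) {
    list(
      mu = par[seq_len(n_mu)],
      sigma = par[n_mu + seq_len(n_sg)],
      lambda = if (n_lm > 0) par[n_mu + n_sg + seq_len(n_lm)] else NULL
    )
  }

  yv <- d$y
  nll <- function(par) {
    p <- split_par(par)
    if (family == "NO") {
      mu <- drop(b_mu$X %*% p$mu)
      sigma <- exp(drop(b_sg$X %*% p$sigma))
      ll <- stats::dnorm(yv, mu, sigma, log = TRUE)
    } else {
      mu <- exp(drop(b_mu$X %*% p$mu))
      sigma <- exp(drop(b_sg$X %*% p$sigma))
      lambda <- drop(b_lm$X %*% p$lambda)
      z <- bccg_z(yv, mu, sigma, lambda)
      ll <- -0.5 * z^2 - log(sigma) - lambda * log(mu) +
        (lambda - 1) * log(yv) - 0.5 * log(2 * pi)
    }
    if (!all(is.finite(ll))) {
      return(1e10)
    }
    -sum(ll)
  }

  # deterministic initialisation
  if (family == "NO") {
    init_mu <- unname(coef(stats::lm.fit(b_mu$X, yv)))
    res <- yv - drop(b_mu$X %*% init_mu)
    init_sg <- c(log(max(sd(res), 1e-6)), rep(0, n_sg - 1))
    par0 <- c(init_mu, init_sg)
  } else {
    init_mu <- unname(coef(stats::lm.fit(b_mu$X, log(yv))))
    res <- log(yv) - drop(b_mu$X %*% init_mu)
    init_sg <- c(log(max(sd(res), 1e-6)), rep(0, n_sg - 1))
    init_lm <- c(1, rep(0, n_lm - 1))
    par0 <- c(init_mu, init_sg, init_lm)
  }

  opt <- optim(par0, nll,
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-12)
  )
  if (opt$convergence != 0) {
    opt2 <- optim(opt$par, nll,
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12)
    )
    if (opt2$value < opt$value) opt <- opt2
  }
  if (!is.finite(opt$value) || opt$value >= 1e10) {
    abort("LMS fit did not converge to a finite likelihood.",
      class = "reachdev_fit_error"
    )
  }
  p <- split_par(opt$par)
  total_df <- n_mu + n_sg + n_lm
  ll <- -opt$value
  structure(
    list(
      family = family,
      coefficients = p,
      bases = list(mu = b_mu, sigma = b_sg, lambda = b_lm),
      df = df, total_df = total_df,
      logLik = ll, aic = -2 * ll + 2 * total_df,
      n = nrow(d), age_range = range(d$age_mo),
      data = d, convergence = opt$convergence
    ),
    class = "lms_fit"
  )
}

#' Evaluate the fitted lambda, mu, sigma curves
#'
#' @param fit An `lms_fit`.
#' @param age_mo Ages (months) within the fitted range.
#' @return Tibble with `age_mo`, `lambda`, `mu`, `sigma`.
#' @export
lms_params <- function(fit, age_mo) {
  if (any(age_mo < fit$age_range[1] - 1e-9 | age_mo > fit$age_range[2] + 1e-9)) {
    abort("Ages outside the fitted range.", class = "reachdev_fit_error")
  }
  mu_lin <- drop(fit$bases$mu$eval(age_mo) %*% fit$coefficients$mu)
  sg_lin <- drop(fit$bases$sigma$eval(age_mo) %*% fit$coefficients$sigma)
  if (fit$family == "NO") {
    tibble(age_mo = age_mo, lambda = 1, mu = mu_lin, sigma = exp(sg_lin))
  } else {
    tibble(
      age_mo = age_mo,
      lambda = drop(fit$bases$lambda$eval(age_mo) %*% fit$coefficients$lambda),
      mu = exp(mu_lin), sigma = exp(sg_lin)
    )
  }
}

#' Percentile reference curves from an LMS fit
#'
#' Maps standard-normal quantiles back to the measurement scale:
#' `mu (1 + lambda sigma z)^(1/lambda)` for BCCG (with the log form at
#' lambda = 0) and `mu + sigma z` for the normal family.
#'
#' @param fit An `lms_fit`.
#' @param age_grid_mo Age grid (months) within the fitted range; default a
#'   1-month grid over the fitted range.
#' @param levels Percentile levels in (0, 100).
#' @return A tibble of class `percentile_table`: `age_mo`, `level`, `value`.
#' @export
percentile_curve <- function(fit, age_grid_mo = NULL,
                             levels = c(1, 5, 10, 25, 50, 75, 90, 95, 99)) {
  if (any(levels <= 0 | levels >= 100)) {
    abort("Percentile levels must lie strictly between 0 and 100.",
      class = "reachdev_fit_error"
    )
  }
  age_grid_mo <- age_grid_mo %||%
    seq(ceiling(fit$age_range[1]), floor(fit$age_range[2]), by = 1)
  par <- lms_params(fit, age_grid_mo)
  out <- tidyr::expand_grid(age_mo = age_grid_mo, level = sort(levels)) |>
    left_join(par, by = "age_mo") |>
    mutate(z = qnorm(.data$level / 100))
  out$value <- if (fit$family == "NO") {
    out$mu + out$sigma * out$z
  } else {
    ifelse(abs(out$lambda) < 1e-4,
      out$mu * exp(out$sigma * out$z),
      out$mu * pmax(1 + out$lambda * out$sigma * out$z, 1e-10)^(1 / out$lambda)
    )
  }
  out <- select(out, "age_mo", "level", "value")
  structure(out,
    family = fit$family,
    class = c("percentile_table", class(out))
  )
}

#' Select the LMS distribution family by AIC
#'
#' Fits each candidate family to the pooled data and returns the fit with
#' the lowest AIC (the losing AICs are kept in the `aic_table` attribute).
#' Responses containing zeros or negative values force the `NO` family, with
#' a warning.
#'
#' @inheritParams fit_lms
#' @param candidates Subset of `c("NO", "BCCG")`.
#' @return The winning `lms_fit` with an `aic_table` attribute.
#' @export
select_family <- function(data, y, age = age_mo, candidates = c("NO", "BCCG"),
                          df = c(mu = 3, sigma = 3, lambda = 1)) {
  candidates <- match.arg(candidates, several.ok = TRUE)
  yv <- dplyr::pull(data, {{ y }})
  if (any(yv[is.finite(yv)] <= 0) && "BCCG" %in% candidates) {
    warn(paste(
      "Response contains zero or negative values;",
      "only the NO family can be fitted."
    ), class = "reachdev_lms_fallback")
    candidates <- "NO"
  }
  fits <- list()
  errors <- list()
  for (fam in candidates) {
    f <- tryCatch(fit_lms(data, {{ y }}, {{ age }}, family = fam, df = df),
      error = function(e) e
    )
    if (inherits(f, "error")) errors[[fam]] <- conditionMessage(f) else fits[[fam]] <- f
  }
  if (!length(fits)) {
    abort(paste0(
      "All candidate families failed: ",
      paste(names(errors), unlist(errors), sep = ": ", collapse = "; ")
    ), class = "reachdev_fit_error")
  }
  aics <- purrr::map_dbl(fits, "aic")
  best <- fits[[names(which.min(aics))]]
  attr(best, "aic_table") <- tibble(family = names(aics), aic = unname(aics))
  best
}

#' Normalised quantile residuals and moment diagnostics
#'
#' Quantile residuals are the standard-normal inverse of the fitted
#' conditional CDF at each observation; under a correct model they are
#' standard normal at every age. The data are split into equal-count age
#' groups and the first four moments of the residuals in each group are
#' compared with their N(0, 1) reference values via z-statistics
#' (`z = sqrt(n) * mean`, `(var - 1) / sqrt(2 / (n - 1))`,
#' `skew / sqrt(6 / n)`, `(kurt - 3) / sqrt(24 / n)`).
#'
#' @param fit An `lms_fit`.
#' @param data Optional data frame with `age_mo` and the fitted response as
#'   `y`; defaults to the data the model was fitted on.
#' @param n_groups Number of equal-count age groups (default 9).
#' @return List with `residuals` (tibble: `age_mo`, `y`, `resid`, `group`)
#'   and `moments` (per-group moment table with z-statistics).
#' @export
quantile_residuals <- function(fit, data = NULL, n_groups = 9) {
  d <- data %||% fit$data
  par <- lms_params(fit, clip(d$age_mo, fit$age_range[1], fit$age_range[2]))
  if (fit$family == "NO") {
    p <- pnorm(d$y, par$mu, par$sigma)
  } else {
    p <- pnorm(bccg_z(d$y, par$mu, par$sigma, par$lambda))
  }
  p <- clip(p, 1e-12, 1 - 1e-12)
  res <- tibble(
    age_mo = d$age_mo, y = d$y, resid = qnorm(p),
    group = dplyr::ntile(d$age_mo, n_groups)
  )
  moments <- res |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      age_lo = min(.data$age_mo), age_hi = max(.data$age_mo),
      mean = mean(.data$resid),
      variance = stats::var(.data$resid),
      skewness = mean((.data$resid - mean(.data$resid))^3) /
        (mean((.data$resid - mean(.data$resid))^2)^1.5),
      kurtosis = mean((.data$resid - mean(.data$resid))^4) /
        (mean((.data$resid - mean(.data$resid))^2)^2),
      .groups = "drop"
    ) |>
    mutate(
      z_mean = sqrt(.data$n) * .data$mean,
      z_variance = (.data$variance - 1) / sqrt(2 / (.data$n - 1)),
      z_skewness = .data$skewness / sqrt(6 / .data$n),
      z_kurtosis = (.data$kurtosis - 3) / sqrt(24 / .data$n)
    )
  list(residuals = res, moments = moments)
}

#' @export
print.lms_fit <- function(x, ...) {
  cat(sprintf(
    "<lms_fit> family %s, n = %d, total df = %d, logLik = %.2f, AIC = %.2f\n",
    x$family, x$n, x$total_df, x$logLik, x$aic
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lms_fit <- function(x, ...) {
  purrr::imap(x$coefficients, function(cf, nm) {
    if (is.null(cf)) {
      return(NULL)
    }
    tibble(parameter = nm, term = seq_along(cf) - 1L, estimate = unname(cf))
  }) |> bind_rows()
}

#' @exportS3Method generics::glance
glance.lms_fit <- function(x, ...) {
  tibble(
    family = x$family, logLik = x$logLik, AIC = x$aic,
    df = x$total_df, nobs = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.lms_fit <- function(object, levels = c(5, 25, 50, 75, 95), ...) {
  pt <- percentile_curve(object, levels = levels)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age_mo, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_line(
      data = pt,
      ggplot2::aes(y = .data$value, group = .data$level, colour = factor(.data$level))
    ) +
    ggplot2::labs(
      x = "Age (months)", y = "Measure", colour = "Percentile",
      title = sprintf("LMS percentile curves (%s family)", object$family)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.percentile_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$age_mo, y = .data$value,
    group = .data$level, colour = factor(.data$level)
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Age (months)", y = "Measure", colour = "Percentile",
      title = "Age-conditional percentile curves"
    ) +
    ggplot2::theme_minimal()
}
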