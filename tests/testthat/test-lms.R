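rbccg <- function(n, mu, sigma, lambda) {
  z <- rnorm(n)
  if (abs(lambda) < 1e-4) mu * exp(sigma * z) else mu * pmax(1 + lambda * sigma * z, 1e-10)^(1 / lambda)
}

test_that("flat normal-family fits recover the sample moments", {
  d <- withr::with_seed(41, tibble::tibble(age_mo = runif(2000, 36, 216), y = rnorm(2000, 10, 2)))
  f <- fit_lms(d, y, family = "NO", df = c(mu = 0, sigma = 0))
  par <- lms_params(f, 100)
  expect_equal(par$mu, 10, tolerance = 0.15)
  expect_equal(par$sigma, 2, tolerance = 0.15)
  expect_equal(par$lambda, 1)
  expect_equal(f$aic, -2 * f$logLik + 2 * f$total_df)
})

test_that("BCCG at lambda = 1 matches the normal-family median", {
  d <- withr::with_seed(43, tibble::tibble(age_mo = runif(1500, 36, 216), y = rnorm(1500, 20, 2)))
  fno <- fit_lms(d, y, family = "NO", df = c(mu = 0, sigma = 0))
  fb <- fit_lms(d, y, family = "BCCG", df = c(mu = 0, sigma = 0, lambda = 0))
  med_no <- percentile_curve(fno, 120, levels = 50)$value
  med_b <- percentile_curve(fb, 120, levels = 50)$value
  expect_equal(med_b, med_no, tolerance = 0.1)
})

test_that("percentile curves follow the normal closed form on flat fits", {
  d <- withr::with_seed(47, tibble::tibble(age_mo = runif(2000, 36, 216), y = rnorm(2000, 10, 2)))
  f <- fit_lms(d, y, family = "NO", df = c(mu = 0, sigma = 0))
  par <- lms_params(f, 120)
  med <- percentile_curve(f, 120, levels = 50)$value
  expect_equal(med, par$mu, tolerance = 1e-9)
  two_sigma <- percentile_curve(f, 120, levels = 100 * pnorm(2))$value
  expect_equal(two_sigma, par$mu + 2 * par$sigma, tolerance = 1e-9)
  expect_error(percentile_curve(f, 120, levels = c(0, 50)), class = "reachdev_fit_error")
  expect_error(lms_params(f, 1000), class = "reachdev_fit_error")
})

test_that("negative responses force the normal family with a warning", {
  d <- withr::with_seed(49, tibble::tibble(age_mo = runif(200, 36, 216), y = rnorm(200, 1, 1)))
  d$y[1] <- -0.5
  expect_warning(f <- fit_lms(d, y, family = "BCCG", df = c(mu = 0, sigma = 0)),
    class = "reachdev_lms_fallback"
  )
  expect_equal(f$family, "NO")
  expect_warning(fs <- select_family(d, y, df = c(mu = 0, sigma = 0)),
    class = "reachdev_lms_fallback"
  )
  expect_equal(fs$family, "NO")
})

test_that("family selection by AIC identifies skewed vs normal data", {
  skewed <- withr::with_seed(53, {
    picks <- replicate(20, {
      d <- tibble::tibble(age_mo = runif(600, 36, 216), y = exp(rnorm(600, 1, 0.6)))
      select_family(d, y, df = c(mu = 0, sigma = 0, lambda = 0))$family
    })
    mean(picks == "BCCG")
  })
  expect_gte(skewed, 0.9)
  normal <- withr::with_seed(59, {
    picks <- replicate(20, {
      d <- tibble::tibble(age_mo = runif(600, 36, 216), y = rnorm(600, 10, 2))
      select_family(d, y, df = c(mu = 0, sigma = 0, lambda = 0))$family
    })
    mean(picks == "NO")
  })
  expect_gte(normal, 0.6)
})

test_that("deviance is non-increasing in the smoothing df", {
  d <- withr::with_seed(61, {
    age <- runif(900, 36, 216)
    tibble::tibble(age_mo = age, y = rnorm(900, 10 + 0.04 * age, 1.5))
  })
  dev <- sapply(c(0, 1, 3, 5), function(k) {
    -2 * fit_lms(d, y, family = "NO", df = c(mu = k, sigma = 1))$logLik
  })
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("quantile residuals are standard normal under the true model", {
  d <- withr::with_seed(67, tibble::tibble(
    age_mo = runif(1800, 36, 216),
    y = rbccg(1800, 20, 0.15, 0.5)
  ))
  f <- fit_lms(d, y, family = "BCCG", df = c(mu = 0, sigma = 0, lambda = 0))
  qr <- quantile_residuals(f)
  expect_equal(nrow(qr$residuals), 1800)
  expect_equal(nrow(qr$moments), 9)
  expect_lt(abs(mean(qr$residuals$resid)), 0.1)
  expect_equal(sd(qr$residuals$resid), 1, tolerance = 0.1)
})

test_that("a mis-specified normal fit on lognormal data shows skewness", {
  d <- withr::with_seed(71, tibble::tibble(
    age_mo = runif(1800, 36, 216),
    y = exp(rnorm(1800, 1, 0.7))
  ))
  f <- fit_lms(d, y, family = "NO", df = c(mu = 0, sigma = 0))
  qr <- quantile_residuals(f)
  expect_gt(mean(abs(qr$moments$z_skewness) > 2), 0.5)
})

test_that("cohort-derived percentile curves put about half the children below the median", {
  e <- default_cohort_epochs()
  d <- e[e$epoch == "end_learning" & e$measure == "initial_angle_deg" &
    e$age_mo < 216, c("age_mo", "mean")]
  names(d) <- c("age_mo", "y")
  f <- suppressWarnings(select_family(d, y, df = c(mu = 2, sigma = 1, lambda = 0)))
  med <- percentile_curve(f, d$age_mo, levels = 50)
  frac <- mean(d$y < med$value[match(d$age_mo, med$age_mo)])
  n <- nrow(d)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n) + 0.02)
  # percentile ordering never crosses on a 1-month grid
  pt <- percentile_curve(f)
  mono <- tapply(pt$value, pt$age_mo, function(v) all(diff(v) > 0))
  expect_true(all(mono))
})
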