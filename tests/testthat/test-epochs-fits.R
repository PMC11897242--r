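make_measures <- function(values, task = "pushball", valid = NULL) {
  n <- sum(task_blocks(task))
  tibble::tibble(
    participant_id = "P1", age_mo = 100, task = task,
    trial_index = seq_len(n),
    valid = valid %||% rep(TRUE, n),
    initial_angle_deg = values,
    final_angle_deg = values,
    compensation_angle_deg = 0
  )
}

test_that("epoch windows land on the adopted block boundaries", {
  w <- epoch_windows("pushball")
  expect_equal(w$trial_index[w$epoch == "baseline"], 11:20)
  expect_equal(w$trial_index[w$epoch == "end_learning"], 101:110)
  expect_equal(w$trial_index[w$epoch == "early_clamp"], 111:113)
  expect_equal(w$trial_index[w$epoch == "end_clamp"], 128:130)
  expect_equal(w$trial_index[w$epoch == "early_washout"], 131:133)
  expect_equal(w$trial_index[w$epoch == "end_washout"], 151:160)
  wl <- epoch_windows("launchball")
  expect_equal(wl$trial_index[wl$epoch == "baseline"], 31:40)
  expect_equal(wl$trial_index[wl$epoch == "end_washout"], 171:180)
})

test_that("epoch summaries average the defined windows", {
  const <- extract_epochs(make_measures(rep(7, 160)))
  ia <- const[const$measure == "initial_angle_deg", ]
  expect_equal(nrow(ia), 6)
  expect_true(all(ia$mean == 7))
  expect_true(all(ia$sd == 0))
  expect_equal(ia$n_trials[ia$epoch == "baseline"], 10)

  idx <- extract_epochs(make_measures(as.numeric(1:160)))
  ia <- idx[idx$measure == "initial_angle_deg", ]
  expect_equal(ia$mean[ia$epoch == "baseline"], mean(11:20))
  expect_equal(ia$mean[ia$epoch == "end_washout"], mean(151:160))
  expect_equal(ia$mean[ia$epoch == "early_clamp"], mean(111:113))
})

test_that("invalid trials are dropped with the trial count decremented", {
  valid <- rep(TRUE, 160)
  valid[12] <- FALSE
  e <- extract_epochs(make_measures(as.numeric(1:160), valid = valid))
  ia <- e[e$measure == "initial_angle_deg" & e$epoch == "baseline", ]
  expect_equal(ia$n_trials, 9)
  expect_equal(ia$mean, mean(setdiff(11:20, 12)))
})

test_that("epoch means ignore row order and participant order", {
  m1 <- make_measures(as.numeric(1:160))
  m2 <- m1
  m2$participant_id <- "P2"
  both <- dplyr::bind_rows(m1, m2)
  shuffled <- withr::with_seed(4, both[sample(nrow(both)), ])
  e1 <- extract_epochs(both)
  e2 <- extract_epochs(shuffled)
  expect_equal(e1, e2)
  expect_error(
    extract_epochs(dplyr::select(m1, -trial_index)),
    class = "reachdev_bad_columns"
  )
})

test_that("noiseless developmental laws are recovered exactly", {
  # noiseless data triggers lm's perfect-fit summary warning; harmless here
  suppressWarnings({
  ages <- seq(40, 210, by = 2)
  inv <- fit_inverse(tibble::tibble(age_mo = ages, y = 25 - 700 / ages), y)
  expect_equal(inv$a, 25, tolerance = 1e-9)
  expect_equal(inv$b, -700, tolerance = 1e-6)
  expect_equal(inv$adj_r2, 1, tolerance = 1e-9)

  const <- fit_inverse(tibble::tibble(age_mo = ages, y = rep(4, length(ages))), y)
  expect_equal(const$a, 4, tolerance = 1e-9)
  expect_equal(const$b, 0, tolerance = 1e-6)

  lg <- fit_log(tibble::tibble(age_mo = ages, y = 2 * log(ages) + 1), y)
  expect_equal(lg$a, 2, tolerance = 1e-9)
  expect_equal(lg$b, 1, tolerance = 1e-6)

  ex <- fit_exponential(tibble::tibble(age_mo = ages, y = 17 * exp(-0.006 * ages)), y)
  expect_equal(ex$a, 17, tolerance = 1e-6)
  expect_equal(ex$b, -0.006, tolerance = 1e-6)

  expect_error(fit_inverse(tibble::tibble(age_mo = c(40, 50), y = c(1, 2)), y),
    class = "reachdev_fit_error"
  )
  expect_error(fit_inverse(tibble::tibble(age_mo = c(0, 40, 50), y = c(1, 2, 3)), y),
    class = "reachdev_fit_error"
  )
  })
})

test_that("Wald intervals contain the point estimates and tidy() mirrors them", {
  ages <- seq(40, 210, by = 5)
  d <- tibble::tibble(age_mo = ages, y = 25 - 700 / ages + withr::with_seed(6, rnorm(length(ages), 0, 2)))
  f <- fit_inverse(d, y)
  expect_true(f$ci_a[1] <= f$a && f$a <= f$ci_a[2])
  expect_true(f$ci_b[1] <= f$b && f$b <= f$ci_b[2])
  td <- tidy(f)
  expect_equal(td$estimate, c(f$a, f$b))
  expect_equal(glance(f)$adj.r.squared, f$adj_r2)
})

test_that("inverse-law confidence intervals are calibrated", {
  cover <- withr::with_seed(17, {
    mean(replicate(500, {
      ages <- runif(60, 40, 212)
      d <- tibble::tibble(age_mo = ages, y = 25 - 700 / ages + rnorm(60, 0, 3))
      f <- fit_inverse(d, y)
      f$ci_a[1] <= 25 && 25 <= f$ci_a[2]
    }))
  })
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("model selection prefers the better fit and breaks ties toward inverse", {
  mk <- function(model, r2) structure(list(model = model, adj_r2 = r2), class = "devcurve_fit")
  expect_equal(select_model(list(mk("inverse", 0.12), mk("logarithmic", 0.10)))$model, "inverse")
  expect_equal(select_model(list(mk("logarithmic", 0.30), mk("inverse", 0.12)))$model, "logarithmic")
  expect_equal(select_model(list(mk("logarithmic", 0.2), mk("inverse", 0.2)))$model, "inverse")
  # order independence and idempotence
  a <- select_model(list(mk("exponential", 0.4), mk("inverse", 0.1)))
  b <- select_model(list(mk("inverse", 0.1), mk("exponential", 0.4)))
  expect_equal(a$model, b$model)
  expect_equal(select_model(list(a))$model, a$model)
})

test_that("data from a logarithmic law mostly selects the log model", {
  hits <- withr::with_seed(23, {
    mean(replicate(100, {
      ages <- runif(80, 40, 212)
      d <- tibble::tibble(age_mo = ages, y = 6 * log(ages) - 10 + rnorm(80, 0, 1))
      select_model(list(fit_inverse(d, y), fit_log(d, y)))$model == "logarithmic"
    }))
  })
  expect_gte(hits, 0.95)
})

test_that("variability summaries reproduce direct SD computations", {
  vals <- withr::with_seed(31, rnorm(160, 10, 3))
  v <- variability_summary(make_measures(vals))
  bl <- v[v$epoch == "baseline" & v$measure == "initial_angle_deg", ]
  expect_equal(bl$sd, sd(vals[11:20]), tolerance = 1e-12)
  el <- v[v$epoch == "end_learning" & v$measure == "final_angle_deg", ]
  expect_equal(el$sd, sd(vals[101:110]), tolerance = 1e-12)
  cv <- variability_summary(make_measures(rep(3, 160)))
  expect_true(all(cv$sd == 0))
})
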