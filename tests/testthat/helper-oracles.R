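# Independent brute-force oracles for the kinematic measures: plain loops
# over samples, no shared code with the package internals beyond the angle
# definition itself.

oracle_angle <- function(x, y) unname(atan2(-x, y) * 180 / pi)

oracle_onset <- function(m) {
  for (i in 2:nrow(m)) {
    if (m[i, 2] != m[i - 1, 2] || m[i, 3] != m[i - 1, 3]) {
      return(unname(m[i, 1]))
    }
  }
  NA_real_
}

oracle_ia <- function(m, thr = 1.2) {
  for (i in seq_len(nrow(m))) {
    if (sqrt(m[i, 2]^2 + m[i, 3]^2) >= thr) {
      return(list(
        angle = oracle_angle(m[i, 2], m[i, 3]),
        time = unname(m[i, 1]) - oracle_onset(m), index = i
      ))
    }
  }
  NULL
}

oracle_fa <- function(m) oracle_angle(m[nrow(m), 2], m[nrow(m), 3])

oracle_plr <- function(m) {
  len <- 0
  for (i in 2:nrow(m)) {
    len <- len + sqrt((m[i, 2] - m[i - 1, 2])^2 + (m[i, 3] - m[i - 1, 3])^2)
  }
  unname(len / sqrt((m[nrow(m), 2] - m[1, 2])^2 + (m[nrow(m), 3] - m[1, 3])^2))
}

oracle_correction <- function(m, thr = 1.2, window = 5) {
  ia <- oracle_ia(m, thr)
  if (is.null(ia) || ia$index >= nrow(m)) {
    return(NULL)
  }
  for (i in (ia$index + 1):nrow(m)) {
    if (abs(oracle_angle(m[i, 2], m[i, 3]) - ia$angle) > window) {
      onset <- oracle_onset(m)
      return(list(
        index = i,
        nct = unname((m[i, 1] - onset) / (m[nrow(m), 1] - onset))
      ))
    }
  }
  NULL
}

oracle_spread <- function(m, thr = 1.2) {
  ia <- oracle_ia(m, thr)
  angs <- sapply(ia$index:nrow(m), function(i) oracle_angle(m[i, 2], m[i, 3]))
  max(angs) - min(angs)
}

# Random piecewise-linear trajectory fixture. Headings wander, radial
# progress is mostly outward, timestamps are irregular; always reaches well
# past the initial-angle threshold.
random_trajectory <- function(n = NULL) {
  n <- n %||% sample(10:40, 1)
  dt <- runif(n - 1, 4, 40)
  t <- cumsum(c(runif(1, 0, 20), dt))
  heading <- cumsum(c(runif(1, -40, 40), rnorm(n - 1, 0, 12)))
  r <- cumsum(c(0, runif(n - 1, 0.05, 1.6)))
  th <- heading * pi / 180
  cbind(t_ms = t, x_gu = -r * sin(th), y_gu = r * cos(th))
}

# Closed-form scalar recursion of the single-rate learner, used as the
# independent linear-system oracle: x' = A x - B e.
oracle_state_sequence <- function(A, B, errors, x0 = 0) {
  x <- numeric(length(errors) + 1)
  x[1] <- x0
  for (k in seq_along(errors)) x[k + 1] <- A * x[k] - B * errors[k]
  x
}

# One-sided permutation test for a negative Spearman correlation.
perm_cor_pvalue <- function(x, y, n_perm = 2000, seed = 123) {
  obs <- cor(x, y, method = "spearman")
  perms <- withr::with_seed(seed, {
    replicate(n_perm, cor(sample(x), y, method = "spearman"))
  })
  list(rho = obs, p = (1 + sum(perms <= obs)) / (n_perm + 1))
}
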