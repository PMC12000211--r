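test_that("start points follow the class-specific distributions", {
  expect_equal(sample_start("diffusion", 0, 5), matrix(0, 5, 2))
  expect_equal(sample_start("accumulator", 0, 3), matrix(0, 3, 2))
  expect_error(sample_start("diffusion", -0.1), "non-negative")

  # diffusion: uniform on the balance axis in [-s_v, s_v]
  s <- sample_start("diffusion", 1, 1e5, seed = 11)
  ax <- option_frame(pi)$u_A
  b <- project(s, ax)
  expect_gt(stats::ks.test(b, stats::punif, -1, 1)$p.value, 0.01)

  # accumulator: independent uniforms per accumulator; the balance
  # (projection difference) is triangular, peaked at zero
  s <- sample_start("accumulator", 1, 1e5, seed = 12)
  bal <- s[, 1] - s[, 2]
  tri_cdf <- function(q) ifelse(q < 0, (1 + q)^2 / 2, 1 - (1 - q)^2 / 2)
  expect_gt(stats::ks.test(bal, tri_cdf)$p.value, 0.01)
  # central mass beats any uniform alternative
  expect_gt(mean(abs(bal) < 0.2), 0.3)
})

test_that("symmetric settings give unbiased choices", {
  # gamma = pi, zero drift
  tr <- simulate_trials(fixed_par(mu_mag = 0, theta = 1), 1e4, seed = 21)
  expect_lt(abs(mean(tr$choice == "A") - 0.5), 3 * 0.005)
  # gamma = pi/2, equal drifts on both accumulators (phi = pi/4)
  tr <- simulate_trials(fixed_par(phi = pi / 4, mu_mag = 1, theta = 1,
                                  gamma = pi / 2), 1e4, seed = 22)
  expect_lt(abs(mean(tr$choice == "A") - 0.5), 3 * 0.005)
})

test_that("gamma = pi simulation matches closed-form Wiener absorption", {
  # 3 x 3 grid of (delta, theta); 1e4 trials per cell, 3 MC SEs
  for (delta in c(0.3, 0.8, 1.5)) {
    for (theta in c(0.6, 1.0, 1.6)) {
      par <- fixed_par(phi = 0, mu_mag = delta, theta = theta)
      tr <- simulate_trials(par, 1e4, seed = round(1000 * delta + theta * 10))
      p_hat <- mean(tr$choice[!tr$censored] == "A")
      p_true <- wiener_absorption_prob(theta, delta)
      se <- sqrt(p_true * (1 - p_true) / sum(!tr$censored))
      expect_lt(abs(p_hat - p_true), 3 * se + 0.005)
    }
  }
})

test_that("mean decision times match the closed-form Wiener expectation", {
  # E[T] = (theta/delta) tanh(theta*delta/sigma^2) for unbiased start.
  # A fine step keeps the first-passage discretization bias (order
  # sigma * sqrt(dt)) below the Monte-Carlo allowance.
  for (delta in c(0.5, 1.5)) {
    theta <- 1
    tr <- simulate_trials(fixed_par(phi = 0, mu_mag = delta, theta = theta),
                          2e4, dt = 2e-4, seed = round(100 * delta))
    et <- (theta / delta) * tanh(theta * delta)
    se <- sd(tr$decision_time) / sqrt(nrow(tr))
    expect_lt(abs(mean(tr$decision_time[!tr$censored]) - et), 3 * se + 0.01)
  }
})

test_that("increasing non-decision time translates RTs exactly", {
  p1 <- fixed_par(tau = 0.2)
  p2 <- fixed_par(tau = 0.45)
  t1 <- simulate_trials(p1, 500, seed = 31)
  t2 <- simulate_trials(p2, 500, seed = 31)
  expect_equal(t2$rt, t1$rt + 0.25, tolerance = 1e-12)
  expect_identical(t1$choice, t2$choice)
})

test_that("choice probabilities converge under dt refinement", {
  par <- fixed_par(phi = 0, mu_mag = 0.8, theta = 1)
  p_coarse <- mean(simulate_trials(par, 1e5, dt = 0.01,
                                   seed = 41)$choice == "A")
  p_fine <- mean(simulate_trials(par, 1e5, dt = 0.001,
                                 seed = 42)$choice == "A")
  expect_lt(abs(p_coarse - p_fine), 3 * sqrt(0.25 / 1e5) * 2)
})

test_that("racing geometry matches an independent 1-D race", {
  # gamma = pi/2 with drift along u_A only: accumulator A is a 1-D
  # diffusion to theta, B an independent zero-drift diffusion
  par <- fixed_par(phi = 0, mu_mag = 1, theta = 1.2, gamma = pi / 2,
                   model_class = "gsr")
  n <- 1e4
  tr <- simulate_trials(par, n, seed = 51)
  tr <- tr[!tr$censored, ]
  # direct vectorized 1-D race oracle on the same step grid
  set.seed(52)
  dt <- 0.001
  a <- b <- numeric(n)
  active <- rep(TRUE, n)
  race_win <- logical(n)
  race_rt <- numeric(n)
  k <- 0L
  while (any(active) && k < 10000L) {
    idx <- which(active)
    a[idx] <- a[idx] + 1 * dt + sqrt(dt) * rnorm(length(idx))
    b[idx] <- b[idx] + sqrt(dt) * rnorm(length(idx))
    k <- k + 1L
    hit <- idx[a[idx] >= 1.2 | b[idx] >= 1.2]
    if (length(hit)) {
      race_win[hit] <- a[hit] >= 1.2 & !(b[hit] >= 1.2 & b[hit] > a[hit])
      race_rt[hit] <- k * dt
      active[hit] <- FALSE
    }
  }
  p_se <- sqrt(0.25 / n)
  expect_lt(abs(mean(tr$choice == "A") - mean(race_win)), 3 * sqrt(2) * p_se)
  t_se <- sd(race_rt) / sqrt(n)
  expect_lt(abs(mean(tr$decision_time) - mean(race_rt)),
            3 * sqrt(2) * t_se + 0.01)
})

test_that("censoring is flagged, not raised", {
  par <- fixed_par(mu_mag = 0, theta = 6)
  tr <- simulate_trials(par, 200, t_max = 0.5, seed = 61)
  expect_true(any(tr$censored))
  expect_true(all(is.na(tr$choice[tr$censored])))
  expect_error(simulate_trials(fixed_par(mu_mag = NaN), 5), "non-finite")
  expect_error(simulate_trials(fixed_par(), 5, dt = -0.1), "dt")
})

test_that("match proportions are computed from the wrapped stimulus model", {
  # perfectly ambiguous match: proportions (.5, .5) and equal expected drifts
  d <- accumulator_drifts_from_match(2, 0, nu = 0)
  expect_equal(attr(d, "proportion"), 0.5, tolerance = 1e-12)
  expect_equal(unname(d["correct"]), unname(d["incorrect"]))
  # mu_mag = 0: both drifts are pure variability draws with mean 0
  set.seed(71)
  draws <- replicate(2000, sum(accumulator_drifts_from_match(0, 0.5, nu = 1)))
  expect_lt(abs(mean(draws)), 3 * sqrt(2) / sqrt(2000))
  # monotone in match level, agreeing with a numeric-integration oracle
  ha <- pi / 12
  sds <- pi / 12
  p <- sapply(c(0, 1 / 3, 2 / 3), favor_proportion, half_angle = ha,
              stim_sd = sds)
  expect_true(all(diff(p) > 0))
  oracle <- sapply(c(0, 1 / 3, 2 / 3), function(m) {
    integrand <- function(x) {
      sapply(x, function(xx) sum(dnorm(xx + 2 * pi * (-5:5),
                                       mean = m * ha, sd = sds)))
    }
    integrate(integrand, 0, pi, rel.tol = 1e-10)$value
  })
  expect_equal(p, oracle, tolerance = 1e-8)
})

test_that("condition maps count free parameters and resolve conditions", {
  # application mapping: 14 free parameters
  base <- list(phi = c(0.2, 0.4, 0.8), mu_mag = matrix(c(1, 2, 1.5, 2.5), 2),
               theta = c(1.5, 1.8), gamma = c(pi / 2, 0.6 * pi),
               tau = 0.3, nu = 0.5, s_v = 0.2)
  cm <- build_condition_parameters(base, design_spec())
  expect_identical(attr(cm, "n_free"), 14L)
  expect_identical(nrow(cm), 12L)
  # mean drift is 0 in the lowest-match conditions
  expect_true(all(cm$mu_mag[cm$match == 0] == 0))
  expect_true(all(cm$mu_mag[cm$match > 0] > 0))
  # tau, nu, s_v shared
  expect_identical(length(unique(cm$tau)), 1L)
  expect_identical(length(unique(cm$nu)), 1L)
  expect_identical(length(unique(cm$s_v)), 1L)
  # single-condition mapping: the five generative parameters + gamma = 6
  ds1 <- single_condition_design()
  base1 <- list(phi = 0.4, mu_mag = 2, theta = 1.5, gamma = pi / 2,
                tau = 0.3, nu = 0.5, s_v = 0)
  expect_identical(attr(build_condition_parameters(base1, ds1), "n_free"), 6L)
  # missing level errors
  expect_error(build_condition_parameters(
    modifyList(base, list(phi = c(0.2, 0.4))), design_spec()), "match")
})

test_that("datasets replicate the design's trial structure", {
  base <- sample_application_parameters("accumulator", seed = 81)
  cm <- build_condition_parameters(base, design_spec())
  tr <- simulate_dataset(cm, seed = 82)
  expect_identical(nrow(tr), 120L)               # 12 conditions x 10 trials
  expect_identical(length(unique(tr$condition)), 12L)
  expect_true(all(table(tr$condition) == 10))
  # 34 participants x 120 trials = 4080
  expect_identical(34L * nrow(tr), 4080L)
  # empty design gives an empty table, no error
  tr0 <- simulate_dataset(cm, trials_per_condition = 0)
  expect_identical(nrow(tr0), 0L)
  # per-trial drift variability is resampled (RTs differ across trials)
  expect_gt(sd(tr$rt), 0)
})

test_that("discrete-sample mode steps one stimulus update at a time", {
  par <- fixed_par(phi = 0, mu_mag = 0.5, theta = 1)
  tr <- simulate_discrete_trials(par, 500, keep_trace = TRUE, seed = 91)
  expect_identical(tr$rt[!tr$censored], as.numeric(tr$n_steps[!tr$censored]))
  # trace sums reproduce the end-of-trial balance (2x for gamma = pi)
  b1 <- vapply(tr$trace, sum, numeric(1))
  expect_equal(b1, 2 * tr$x, tolerance = 1e-9)
})
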