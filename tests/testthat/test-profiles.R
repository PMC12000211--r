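test_that("profiles are normalized histograms", {
  pr <- evidence_profile(rnorm(500), n_bins = 31)
  expect_equal(sum(pr$mass), 1, tolerance = 1e-9)
  expect_length(pr$mass, 31)
  expect_error(evidence_profile(numeric(0)), "finite")
  expect_error(evidence_profile(1:5, breaks = c(1, 1)), "binning")
})

test_that("constant traces give a point mass", {
  tr <- data.frame(censored = FALSE)[rep(1, 20), , drop = FALSE]
  tr$trace <- replicate(20, rep(0.3, 7), simplify = FALSE)
  pr <- profile_from_trials(tr, normalize = TRUE, n_bins = 11)
  expect_equal(max(pr$mass), 1)
  expect_equal(pr$mids[which.max(pr$mass)], 0.3, tolerance = 0.1)
  # missing trace names the trial
  tr$trace[[3]] <- numeric(0)
  expect_error(profile_from_trials(tr), "trial")
})

test_that("relative-evidence profiles are bimodal with a central gap", {
  par <- fixed_par(phi = 0, mu_mag = 1, theta = 2)
  tr <- simulate_discrete_trials(par, 1e4, seed = 201)
  pr <- profile_from_trials(tr, n_bins = 61)
  m <- pr$mids
  lim <- 0.15 * max(abs(m))
  central <- sum(pr$mass[abs(m) < lim])
  flank <- max(sum(pr$mass[m >= lim & m < 3 * lim]),
               sum(pr$mass[m <= -lim & m > -3 * lim]))
  expect_lt(central, flank)  # under-sampled moderate evidence
  # accumulator profile approximates the stimulus distribution more
  # closely than the diffusion profile does (smaller K-L)
  para <- fixed_par(phi = 0.3, mu_mag = 0.5, theta = 2, gamma = pi / 2,
                    model_class = "gsr")
  tra <- simulate_discrete_trials(para, 1e4, seed = 202)
  bal_a <- normalized_balance(tra, pi / 2)
  trd <- simulate_discrete_trials(fixed_par(phi = 0.3, mu_mag = 0.5 * sqrt(2),
                                            theta = 2), 1e4, seed = 203)
  bal_d <- normalized_balance(trd, pi)
  # the "true" profile: unconditional per-trial averages of the stimulus
  # balance increments over the same trial lengths
  set.seed(204)
  true_a <- sapply(tra$n_steps[!tra$censored], function(n)
    mean(rnorm(n, 0.5 * (cos(0.3) - sin(0.3)), sqrt(2))))
  true_d <- sapply(trd$n_steps[!trd$censored], function(n)
    mean(rnorm(n, 2 * 0.5 * sqrt(2) * cos(0.3), 2)))
  rng <- range(bal_a, true_a)
  br <- seq(rng[1], rng[2], length.out = 62)
  kl_a <- kl_divergence(evidence_profile(bal_a, br),
                        evidence_profile(true_a, br))
  rng <- range(bal_d, true_d)
  br <- seq(rng[1], rng[2], length.out = 62)
  kl_d <- kl_divergence(evidence_profile(bal_d, br),
                        evidence_profile(true_d, br))
  expect_lt(kl_a, kl_d)
  # diffusion-class profile variance exceeds the true distribution's
  expect_gt(var(bal_d), var(true_d))
})

test_that("wiener densities integrate to the absorption probabilities", {
  # symmetry at zero drift
  d <- wiener_fpt_density(c(0.2, 0.7, 1.9), theta = 1, delta = 0)
  expect_equal(d$upper, d$lower, tolerance = 1e-10)
  expect_error(wiener_fpt_density(c(-1, 1), 1, 0), "positive")
  for (cfg in list(c(1, 0.5, 0.5), c(0.7, 1.5, 0.5), c(1.4, -0.6, 0.3),
                   c(2, 0, 0.5))) {
    up <- integrate(function(t)
      wiener_fpt_density(t, cfg[1], cfg[2], cfg[3])$upper,
      0, Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t)
      wiener_fpt_density(t, cfg[1], cfg[2], cfg[3])$lower,
      0, Inf, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, wiener_absorption_prob(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-4)
  }
})

test_that("continuous profiles are bimodal with no mass at zero", {
  pr <- ddm_continuous_profile(1, 0.5, t_grid = seq(0.01, 30, by = 0.01))
  expect_equal(sum(pr$mass), 1, tolerance = 1e-9)
  expect_true(all(pr$support != 0))
  # positive-branch mass equals the analytic absorption probability
  expect_equal(pr$upper_mass, wiener_absorption_prob(1, 0.5),
               tolerance = 1e-3)
  # symmetric when drift is zero
  pr0 <- ddm_continuous_profile(1, 0, t_grid = seq(0.01, 30, by = 0.01))
  expect_equal(pr0$upper_mass, 0.5, tolerance = 1e-3)
  expect_error(ddm_continuous_profile(1, 0.5, t_grid = c(2, 1)), "grid")
  # cross-module consistency: branch mass ratio matches the simulator
  tr <- simulate_trials(fixed_par(phi = 0, mu_mag = 0.5, theta = 1), 2e4,
                        seed = 211)
  p_sim <- mean(tr$choice[!tr$censored] == "A")
  expect_lt(abs(pr$upper_mass - p_sim), 3 * sqrt(0.25 / 2e4) + 0.005)
})

test_that("bimodality coefficient matches its analytic benchmarks", {
  # balanced two-point sample: B -> 1
  expect_equal(bimodality_coefficient(rep(c(-1, 1), 1000)), 1,
               tolerance = 0.01)
  # uniform: B -> 5/9 (skew 0, excess kurtosis -1.2)
  set.seed(221)
  expect_equal(bimodality_coefficient(runif(1e5)), 5 / 9, tolerance = 0.02)
  # normal: B -> 1/3
  expect_equal(bimodality_coefficient(rnorm(1e5)), 1 / 3, tolerance = 0.02)
  # matches a hand computation of the SAS-style estimators
  x <- c(0.3, -1.2, 2.5, 0.1, 0.9, -0.4, 1.7)
  n <- length(x)
  z <- (x - mean(x)) / sd(x)
  g <- n / ((n - 1) * (n - 2)) * sum(z^3)
  k <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  expect_equal(bimodality_coefficient(x),
               (g^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3))),
               tolerance = 1e-12)
  # location/scale invariance
  set.seed(222)
  y <- rexp(500)
  expect_equal(bimodality_coefficient(y),
               bimodality_coefficient(-2.5 * y + 7), tolerance = 1e-12)
  expect_error(bimodality_coefficient(c(1, 2, 3)), "more than 3")
  expect_warning(B0 <- bimodality_coefficient(rep(1, 10)), "zero-variance")
  expect_true(is.na(B0))
})

test_that("K-L divergence behaves as a divergence", {
  set.seed(231)
  x <- rnorm(2000)
  br <- seq(-4, 4, length.out = 42)
  p <- evidence_profile(x, breaks = br)
  expect_equal(kl_divergence(p, p, smooth = FALSE), 0)
  # independent plug-in computation on random histograms
  y <- rnorm(2000, 0.4)
  q <- evidence_profile(y, breaks = br)
  qs <- q$mass + 1 / (q$n * length(q$mass))
  qs <- qs / sum(qs)
  manual <- sum(ifelse(p$mass > 0, p$mass * log(p$mass / qs), 0))
  expect_equal(kl_divergence(p, q), manual, tolerance = 1e-12)
  expect_gte(kl_divergence(p, q), 0)
  # point mass against smoothed epsilon bin
  pm <- evidence_profile(rep(0.5, 100), breaks = c(0, 1, 2, 3))
  q0 <- evidence_profile(rep(2.5, 50), breaks = c(0, 1, 2, 3))
  eps <- (1 / (50 * 3)) / (1 + 3 / (50 * 3))
  expect_equal(kl_divergence(pm, q0), log(1 / eps), tolerance = 1e-12)
  # mismatched bins error
  p2 <- evidence_profile(x, breaks = seq(-4, 4, length.out = 30))
  expect_error(kl_divergence(p, p2), "breaks")
})

test_that("the option angle is recovered by K-L over a model grid", {
  grid <- seq(pi / 8, pi, length.out = 8)
  mk <- function(g) fixed_par(phi = 0.3, mu_mag = 1, theta = 2, nu = 0.3,
                              gamma = g, model_class = "gsr")
  models <- lapply(seq_along(grid), function(i)
    normalized_balance(simulate_discrete_trials(mk(grid[i]), 6000,
                                                seed = 300 + i), grid[i]))
  # identical profile: returns that grid gamma with (smoothed) KL ~ 0 there
  f0 <- fit_gamma_by_kl(models[[4]], models, grid)
  expect_equal(f0$kl[4], 0, tolerance = 1e-3)
  expect_identical(which.min(f0$kl), 4L)
  expect_equal(f0$gamma, grid[4], tolerance = diff(grid)[1] / 2)
  # self-consistency at gamma = pi/2 within one grid spacing
  obs <- normalized_balance(simulate_discrete_trials(mk(pi / 2), 6000,
                                                     seed = 310), pi / 2)
  f1 <- fit_gamma_by_kl(obs, models, grid)
  expect_lt(abs(f1$gamma - pi / 2), diff(grid)[1])
  # generating at the gamma = pi edge: estimate near pi or boundary-flagged
  obs2 <- normalized_balance(simulate_discrete_trials(mk(pi), 6000,
                                                      seed = 311), pi)
  f2 <- fit_gamma_by_kl(obs2, models, grid)
  expect_true(f2$boundary || abs(f2$gamma - pi) < diff(grid)[1])
  expect_error(fit_gamma_by_kl(obs, models[1:3], grid[1:3]), "4 grid")
})

test_that("profiles round-trip through their CSV format", {
  set.seed(241)
  pr <- evidence_profile(rnorm(300), n_bins = 21)
  path <- tempfile(fileext = ".csv")
  write_profile(pr, path)
  pr2 <- read_profile(path)
  expect_equal(pr2$mass, pr$mass, tolerance = 1e-12)
  expect_equal(pr2$breaks, pr$breaks, tolerance = 1e-12)
  expect_identical(pr2$n, pr$n)
  expect_identical(pr2$normalized, pr$normalized)
})
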