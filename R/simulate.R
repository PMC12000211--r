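#' Sample trial start states
#'
#' Start-point distributions differ by model class. The diffusion class
#' assumes a uniform distribution of starting points over the balance of
#' evidence: the start lies on the balance axis, uniform in
#' \code{[-s_v, s_v]}. The accumulator and gsr classes draw an independent
#' uniform start in \code{[0, s_v]} for each accumulator and place the
#' state at \code{a * u_A + b * u_B}; projected onto the balance axis this
#' is triangular, peaked at zero, because many combinations of the two
#' uniforms yield a balanced start while only one yields an extreme one.
#'
#' @param model_class One of \code{"diffusion"}, \code{"accumulator"},
#'   \code{"gsr"}.
#' @param s_v Start-point variability half-width (>= 0).
#' @param n Number of draws.
#' @param frame An [option_frame()]; defaults to the class's canonical
#'   geometry.
#' @param seed Optional integer seed.
#' @return An \code{n x 2} matrix of start states.
#' @export
sample_start <- function(model_class = c("diffusion", "accumulator", "gsr"),
                         s_v, n = 1, frame = NULL, seed = NULL) {
  model_class <- match.arg(model_class)
  stopifnot(is.numeric(s_v), length(s_v) == 1L)
  if (s_v < 0) stop("`s_v` must be non-negative")
  if (is.null(frame)) {
    frame <- option_frame(switch(model_class, diffusion = pi,
                                 accumulator = pi / 2, gsr = pi / 2))
  }
  with_seed(seed, {
    if (s_v == 0) return(matrix(0, n, 2))
    if (model_class == "diffusion") {
      b <- runif(n, -s_v, s_v)
      ax <- balance_axis(frame)
      cbind(b * ax[1], b * ax[2])
    } else {
      a <- runif(n, 0, s_v)
      b <- runif(n, 0, s_v)
      cbind(a * frame$u_A[1] + b * frame$u_B[1],
            a * frame$u_A[2] + b * frame$u_B[2])
    }
  })
}

# Per-trial drift vectors including across-trial variability, plus the
# correct option implied by the mean drift. `par` is a one-row slice of a
# parameter_table (or any list with the same fields).
trial_drifts <- function(par, n) {
  gamma <- par$gamma
  if (identical(par$model_class, "diffusion") ||
      (is.null(par$model_class) && isTRUE(all.equal(gamma, pi)))) {
    # 1-D drift along the balance axis (u_A for gamma = pi), perturbed as a whole
    delta <- par$mu_mag * cos(par$phi) + rnorm(n, 0, par$nu)
    mx <- delta
    my <- rep(0, n)
    mean_pA <- par$mu_mag * cos(par$phi)
    mean_pB <- -mean_pA
  } else {
    uB <- c(cos(gamma), sin(gamma))
    base <- par$mu_mag * c(cos(par$phi), sin(par$phi))
    eta_A <- rnorm(n, 0, par$nu)
    eta_B <- rnorm(n, 0, par$nu)
    mx <- base[1] + eta_A * 1 + eta_B * uB[1]
    my <- base[2] + eta_B * uB[2]
    mean_pA <- base[1]
    mean_pB <- base[1] * uB[1] + base[2] * uB[2]
  }
  list(mu_x = mx, mu_y = my,
       correct = if (mean_pA >= mean_pB) "A" else "B")
}

# Fast internal path: raw vectors, no data.frame construction.
simulate_raw <- function(par, n, dt, t_max, keep_trace = FALSE) {
  stopifnot(n >= 0)
  if (n == 0) {
    return(list(choice = character(0), rt = numeric(0),
                decision_time = numeric(0), n_steps = integer(0),
                censored = logical(0), x = numeric(0), y = numeric(0),
                correct = logical(0)))
  }
  for (f in c("mu_mag", "theta", "tau", "nu", "gamma", "sigma", "s_v")) {
    if (!is.finite(par[[f]])) stop("non-finite parameter `", f, "`")
  }
  if (dt <= 0) stop("`dt` must be positive")
  if (t_max <= par$tau) stop("`t_max` must exceed the non-decision time")
  mc <- if (is.null(par$model_class)) "gsr" else par$model_class
  frame <- option_frame(par$gamma)
  start <- sample_start(mc, par$s_v, n, frame)
  dr <- trial_drifts(par, n)
  sim <- simulate_core(dr$mu_x, dr$mu_y, rep(par$theta, n),
                       rep(par$gamma, n), start[, 1], start[, 2],
                       dt, t_max, par$sigma, keep_trace)
  choice <- c("A", "B")[sim$choice + 1L]
  out <- list(choice = choice,
              rt = sim$rt + par$tau,
              decision_time = sim$rt,
              n_steps = sim$n_steps,
              censored = sim$censored,
              x = sim$x, y = sim$y,
              correct = !sim$censored & choice == dr$correct)
  if (keep_trace) out$trace <- sim$trace
  out
}

#' Simulate trials from one parameter set
#'
#' Runs the two-dimensional accumulation process by Euler--Maruyama
#' stepping: each step adds \code{drift * dt} plus an independent
#' bivariate normal increment with standard deviation \code{sigma *
#' sqrt(dt)} per coordinate. After each step the state is projected onto
#' both option directions; the first projection to reach the threshold
#' \code{theta} triggers the corresponding choice, same-step double
#' crossings are broken by the larger projection, and trials that reach
#' \code{t_max} are flagged censored rather than raising an error.
#' Across-trial drift variability \code{nu} is resampled per trial: as a
#' perturbation of the one-dimensional drift for the diffusion class and
#' as independent perturbations along each option direction otherwise.
#' Reported response times add the non-decision time \code{tau} to the
#' decision time.
#'
#' @param par A one-row [sample_parameters()] table (or a list with fields
#'   \code{phi, mu_mag, theta, tau, nu, gamma, sigma, s_v, model_class}).
#' @param n Number of trials.
#' @param dt Integration step, seconds.
#' @param t_max Simulation horizon, seconds.
#' @param keep_trace If \code{TRUE}, attach a list-column of per-step
#'   balance-of-evidence increments for each trial (memory-heavy; intended
#'   for evidence-profile work at frame-rate resolution).
#' @param seed Optional integer seed.
#' @return A \code{data.frame} with one row per trial: \code{choice}
#'   ("A"/"B", \code{NA} if censored), \code{rt}, \code{decision_time},
#'   \code{n_steps}, \code{censored}, final state \code{x}, \code{y},
#'   \code{correct}, and optionally \code{trace}.
#' @examples
#' par <- sample_parameters(1, "diffusion", seed = 2)
#' head(simulate_trials(par, 10, seed = 3))
#' @export
simulate_trials <- function(par, n, dt = 0.001, t_max = 10,
                            keep_trace = FALSE, seed = NULL) {
  if (inherits(par, "data.frame")) {
    stopifnot(nrow(par) == 1L)
    par <- as.list(par)
  }
  with_seed(seed, {
    raw <- simulate_raw(par, n, dt, t_max, keep_trace)
    out <- data.frame(choice = raw$choice, rt = raw$rt,
                      decision_time = raw$decision_time,
                      n_steps = raw$n_steps, censored = raw$censored,
                      x = raw$x, y = raw$y, correct = raw$correct,
                      stringsAsFactors = FALSE)
    if (keep_trace) out$trace <- raw$trace
    attr(out, "par") <- par
    out
  })
}

#' Simulate a single trial
#'
#' Convenience wrapper around [simulate_trials()] for one trial.
#'
#' @inheritParams simulate_trials
#' @return A one-row trial data.frame.
#' @export
simulate_trial <- function(par, dt = 0.001, t_max = 10,
                           keep_trace = FALSE, seed = NULL) {
  simulate_trials(par, 1L, dt = dt, t_max = t_max,
                  keep_trace = keep_trace, seed = seed)
}

#' Simulate trials as a discrete-sample random walk
#'
#' Accumulated-evidence profiles operate on discrete stimulus updates:
#' each step of the walk is one update contributing an evidence increment
#' with mean \code{drift} and SD \code{sigma} per sample, and the
#' normalized profile divides the end-of-trial balance by the number of
#' updates. This wrapper runs [simulate_trials()] with a unit time base
#' (one time unit = one sample), so \code{theta} and \code{sigma} are in
#' per-sample evidence units and \code{n_steps} counts stimulus updates.
#'
#' @inheritParams simulate_trials
#' @param max_samples Censoring horizon in samples.
#' @return A trial table; \code{rt} is in samples.
#' @export
simulate_discrete_trials <- function(par, n, max_samples = 2000,
                                     keep_trace = FALSE, seed = NULL) {
  simulate_trials(par, n, dt = 1, t_max = max_samples,
                  keep_trace = keep_trace, seed = seed)
}
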