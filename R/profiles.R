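#' Accumulated-evidence profile (histogram container)
#'
#' A distribution of end-of-trial balance-of-evidence values. Profiles are
#' stored as histograms over an equal-width grid so that two profiles
#' built on the same breaks can be compared by K-L divergence.
#'
#' @param values Numeric vector of per-trial balance values.
#' @param breaks Bin breaks; computed from the range of \code{values}
#'   (\code{n_bins} equal-width bins) when \code{NULL}.
#' @param n_bins Number of bins when \code{breaks} is \code{NULL};
#'   default 61.
#' @param normalized Flag recording whether values were divided by the
#'   number of samples/time (average evidence) or left cumulative.
#' @return An object of class \code{"evidence_profile"}: list with
#'   \code{breaks}, \code{mids}, \code{mass} (sums to 1), \code{n},
#'   \code{normalized}.
#' @export
evidence_profile <- function(values, breaks = NULL, n_bins = 61,
                             normalized = TRUE) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  if (is.null(breaks)) {
    r <- range(values)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  }
  if (length(breaks) < 2L || is.unsorted(breaks, strictly = TRUE)) {
    stop("invalid binning")
  }
  cnt <- graphics::hist(pmin(pmax(values, breaks[1]),
                             breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)$counts
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 mass = cnt / sum(cnt),
                 n = length(values),
                 normalized = isTRUE(normalized)),
            class = "evidence_profile")
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat(sprintf("<evidence_profile> %d bins on [%.3g, %.3g], n = %d, %s\n",
              length(x$mass), x$breaks[1], x$breaks[length(x$breaks)],
              x$n, if (x$normalized) "normalized" else "cumulative"))
  invisible(x)
}

#' Profile of end-of-trial balance of evidence from simulated trials
#'
#' For each trial, the accumulated balance of evidence (the projection
#' difference \eqn{comp_A - comp_B} of the final state, or the sum of the
#' stored per-step balance increments when a \code{trace} column is
#' present) is optionally divided by the number of evidence samples, and
#' the per-trial values are collected into a histogram. Relative-evidence
#' stopping (\eqn{\gamma = \pi}) under-samples moderate evidence, so the
#' normalized profile is bimodal with a gap near zero; absolute-evidence
#' stopping (\eqn{\gamma = \pi/2}) yields a profile close to the
#' generating stimulus distribution.
#'
#' @param trials Trial table from [simulate_trials()] /
#'   [simulate_dataset()]. Censored trials are dropped.
#' @param normalize Divide each trial's balance by its number of samples.
#' @param breaks,n_bins Binning, as in [evidence_profile()].
#' @param use_trace Use the stored \code{trace} column (error if absent);
#'   by default traces are used when available and the final state
#'   otherwise.
#' @return An [evidence_profile()].
#' @export
profile_from_trials <- function(trials, normalize = TRUE, breaks = NULL,
                                n_bins = 61, use_trace = NULL) {
  if (!is.null(trials$censored)) trials <- trials[!trials$censored, ]
  if (!nrow(trials)) stop("no uncensored trials")
  has_trace <- !is.null(trials$trace)
  if (is.null(use_trace)) use_trace <- has_trace
  if (use_trace) {
    if (!has_trace) stop("trials carry no `trace` column")
    bad <- vapply(trials$trace, function(t) is.null(t) || !length(t),
                  logical(1))
    if (any(bad)) {
      stop("missing trace for trial(s) ",
           paste(head(which(bad), 5L), collapse = ", "))
    }
    bal <- vapply(trials$trace, sum, numeric(1))
    ns <- vapply(trials$trace, length, numeric(1))
  } else {
    par <- attr(trials, "par")
    gam <- if (!is.null(trials$gamma)) trials$gamma
           else if (!is.null(par)) par$gamma
           else stop("cannot recover the option angle for these trials")
    bal <- balance_of(trials$x, trials$y, gam)
    ns <- trials$n_steps
  }
  vals <- if (normalize) bal / pmax(ns, 1L) else bal
  evidence_profile(vals, breaks = breaks, n_bins = n_bins,
                   normalized = normalize)
}

#' Two-boundary Wiener first-passage-time densities
#'
#' First-passage-time densities of a Wiener process with drift
#' \code{delta} and diffusion SD \code{sigma} between absorbing boundaries
#' at \eqn{-\theta} and \eqn{+\theta}, starting at relative position
#' \code{beta} (0 = lower boundary, 1 = upper; 0.5 = balanced). Evaluated
#' by series expansion with small-time/large-time representation
#' switching, each series truncated to absolute tolerance \code{1e-7}.
#' The density pair integrates to 1 over \eqn{t > 0}, splitting total mass
#' between boundaries according to the absorption probabilities.
#'
#' @param t Positive times (decision times; add non-decision time
#'   externally).
#' @param theta Threshold (> 0), so the boundary separation is
#'   \code{2 * theta}.
#' @param delta Drift rate along the balance axis.
#' @param beta Relative start point in (0, 1).
#' @param sigma Diffusion SD (> 0).
#' @return A list with numeric vectors \code{upper} and \code{lower}, the
#'   densities of first absorption at \eqn{+\theta} and \eqn{-\theta}.
#' @export
wiener_fpt_density <- function(t, theta, delta, beta = 0.5, sigma = 1) {
  stopifnot(theta > 0, sigma > 0, beta > 0, beta < 1)
  if (any(t <= 0)) stop("`t` must be positive")
  a <- 2 * theta / sigma
  v <- delta / sigma
  list(upper = vapply(t, fpt_one, numeric(1), v = -v, a = a, w = 1 - beta),
       lower = vapply(t, fpt_one, numeric(1), v = v, a = a, w = beta))
}

# Density of first passage at the LOWER boundary for a unit-diffusion
# Wiener process on (0, a), start a*w, drift v, evaluated at time t.
fpt_one <- function(t, v, a, w, tol = 1e-7) {
  q <- t / a^2
  pref <- exp(-v * a * w - v^2 * t / 2) / a^2
  if (pref == 0) return(0)
  # representation choice: terms needed for `tol/pref` accuracy in f0(q, w)
  eps <- tol / pref
  # large-time terms needed (Navarro & Fuss style bound)
  kl <- if (pi * q * eps < 1) {
    max(sqrt(-2 * log(pi * q * eps) / (pi^2 * q)), 1 / (pi * sqrt(q)))
  } else 1 / (pi * sqrt(q))
  # small-time terms needed
  ks <- if (2 * sqrt(2 * pi * q) * eps < 1) {
    2 + sqrt(-2 * q * log(2 * eps * sqrt(2 * pi * q)))
  } else 2
  if (ks < kl) {
    K <- ceiling(ks)
    k <- seq.int(-K, K)
    f0 <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * q))) /
      sqrt(2 * pi * q^3)
  } else {
    K <- ceiling(kl)
    k <- seq_len(K)
    f0 <- pi * sum(k * exp(-k^2 * pi^2 * q / 2) * sin(k * pi * w))
  }
  max(pref * f0, 0)
}

#' Two-boundary absorption probability
#'
#' Closed-form probability that the Wiener process of
#' [wiener_fpt_density()] is absorbed at the upper boundary
#' \eqn{+\theta}.
#'
#' @inheritParams wiener_fpt_density
#' @return Probability of upper-boundary absorption.
#' @export
wiener_absorption_prob <- function(theta, delta, beta = 0.5, sigma = 1) {
  stopifnot(theta > 0, sigma > 0, beta > 0, beta < 1)
  a <- 2 * theta / sigma
  v <- delta / sigma
  if (abs(v) < 1e-12) return(beta)
  z <- a * beta
  (1 - exp(-2 * v * z)) / (1 - exp(-2 * v * a))
}

#' Continuous diffusion-model evidence profile
#'
#' The infinitesimal steps of a diffusion process make it stop at exactly
#' \eqn{\pm\theta}, so the normalized balance of evidence at the moment of
#' choice is \eqn{+\theta/t} for upper-boundary (correct) responses and
#' \eqn{-\theta/t} for lower-boundary responses, weighted by the
#' first-passage density of the corresponding boundary. The resulting
#' support never includes zero: the relative-evidence stopping rule
#' filters out balanced evidence states, and the profile is starkly
#' bimodal.
#'
#' @param theta,delta,beta,sigma As in [wiener_fpt_density()].
#' @param tau Non-decision time; shifts the normalizing time base when
#'   positive (balance is divided by decision time plus \code{tau}).
#' @param t_grid Positive, strictly increasing grid of decision times.
#' @return A list of class \code{"evidence_profile"} with \code{support}
#'   (the \eqn{\pm\theta/t} points), \code{mass} (sums to 1), and
#'   \code{upper_mass}, the total mass on the positive branch.
#' @export
ddm_continuous_profile <- function(theta, delta, beta = 0.5, tau = 0,
                                   sigma = 1,
                                   t_grid = seq(0.01, 20, by = 0.01)) {
  if (length(t_grid) < 2L || any(t_grid <= 0) || is.unsorted(t_grid,
                                                             strictly = TRUE)) {
    stop("degenerate time grid")
  }
  dens <- wiener_fpt_density(t_grid, theta, delta, beta, sigma)
  # trapezoid quadrature weights on the grid
  wts <- diff(t_grid)
  wts <- c(wts / 2, 0) + c(0, wts / 2)
  m_up <- dens$upper * wts
  m_lo <- dens$lower * wts
  support <- c(-theta / (t_grid + tau), theta / (rev(t_grid) + tau))
  mass <- c(m_lo, rev(m_up))
  tot <- sum(mass)
  if (tot <= 0) stop("no probability mass on the supplied grid")
  structure(list(support = support, mass = mass / tot,
                 upper_mass = sum(m_up) / tot,
                 n = length(t_grid), normalized = TRUE),
            class = c("ddm_profile", "evidence_profile"))
}

#' Sarle's bimodality coefficient
#'
#' \deqn{B = \frac{g^2 + 1}{k + \frac{3(n-1)^2}{(n-2)(n-3)}}}
#' where \eqn{g} is the bias-adjusted sample skewness, \eqn{k} the
#' bias-adjusted sample excess kurtosis (SAS-style estimators, consistent
#' with the n-correction term in the denominator) and \eqn{n} the sample
#' size. \eqn{B} ranges over (0, 1]: about 1/3 for a normal sample, 5/9
#' for a uniform sample, and 1 for a distribution concentrated on exactly
#' two values. Location- and scale-invariant.
#'
#' @param x Numeric sample with more than 3 finite values.
#' @return The coefficient \eqn{B}, or \code{NA} with a warning for a
#'   zero-variance sample (undefined moments).
#' @examples
#' bimodality_coefficient(rep(c(-1, 1), 500))  # ~1
#' @export
bimodality_coefficient <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n <= 3L) stop("need more than 3 finite values")
  if (sd(x) == 0) {
    warning("zero-variance sample: bimodality coefficient undefined")
    return(NA_real_)
  }
  g <- e1071::skewness(x, type = 2)
  k <- e1071::kurtosis(x, type = 2)
  (g^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Kullback--Leibler divergence between evidence profiles
#'
#' \eqn{\sum_i p_i \log(p_i / q_i)} over shared bins (natural log). The
#' reference profile \code{q} is additively smoothed by \code{1 / (n *
#' n_bins)} (then renormalized) so that no bin has zero mass; the
#' divergence is then finite, non-negative, and zero only for identical
#' histograms.
#'
#' @param p,q [evidence_profile()] objects built on identical breaks.
#' @param smooth Apply additive smoothing to \code{q}.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p, q, smooth = TRUE) {
  stopifnot(inherits(p, "evidence_profile"), inherits(q, "evidence_profile"))
  if (length(p$breaks) != length(q$breaks) ||
      max(abs(p$breaks - q$breaks)) > 1e-9) {
    stop("profiles are binned on different breaks")
  }
  qm <- q$mass
  if (smooth) {
    qm <- qm + 1 / (max(q$n, 1L) * length(qm))
    qm <- qm / sum(qm)
  }
  idx <- p$mass > 0
  if (any(qm[idx] == 0)) stop("reference profile has empty bins; smooth it")
  sum(p$mass[idx] * log(p$mass[idx] / qm[idx]))
}

#' Identify the option angle by K-L divergence over a model grid
#'
#' Computes the K-L divergence between the observed profile and a
#' simulated profile for each grid value of \eqn{\gamma}, interpolates the
#' (\eqn{\gamma}, K-L) points with a cubic spline, and returns the
#' minimizer of the spline within the grid range (dense evaluation over
#' 10^4 points, which avoids derivative-root edge cases). A minimizer that
#' clips to the edge of the grid is flagged.
#'
#' @param observed Numeric vector of observed normalized balance values,
#'   or an [evidence_profile()] (then \code{models} must be profiles on
#'   the same breaks).
#' @param models List of numeric vectors (or profiles) of model-predicted
#'   balance values, one per grid point.
#' @param gamma_grid Option-angle grid, radians; at least 4 points. The
#'   study grid runs evenly from \eqn{\pi/8} to \eqn{\pi} in 8 steps.
#' @param n_bins Shared binning when raw values are supplied.
#' @return List of class \code{"gamma_fit"}: \code{gamma} (the estimate),
#'   \code{boundary} flag, \code{gamma_grid}, \code{kl} (per-grid
#'   divergences).
#' @export
fit_gamma_by_kl <- function(observed, models,
                            gamma_grid = seq(pi / 8, pi, length.out = 8),
                            n_bins = 61) {
  if (length(gamma_grid) < 4L) stop("need at least 4 grid points")
  stopifnot(length(models) == length(gamma_grid),
            !is.unsorted(gamma_grid, strictly = TRUE))
  if (inherits(observed, "evidence_profile")) {
    p <- observed
    profs <- models
  } else {
    pooled <- range(unlist(c(list(observed), models)), finite = TRUE)
    breaks <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
    p <- evidence_profile(observed, breaks = breaks)
    profs <- lapply(models, evidence_profile, breaks = breaks)
  }
  kl <- vapply(profs, function(q) kl_divergence(p, q), numeric(1))
  sp <- splinefun(gamma_grid, kl, method = "fmm")
  xs <- seq(gamma_grid[1], gamma_grid[length(gamma_grid)],
            length.out = 1e4)
  ys <- sp(xs)
  i <- which.min(ys)
  structure(list(gamma = xs[i],
                 boundary = i == 1L || i == length(xs),
                 gamma_grid = gamma_grid, kl = kl, spline_min = ys[i]),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> gamma = %.4f rad (%.3f pi)%s\n", x$gamma,
              x$gamma / pi, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
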