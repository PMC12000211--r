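#' Prior specification for simulated participants
#'
#' Hyperparameters of the generative priors used to draw one simulated
#' participant's parameters. Gamma families are in shape--scale form. The
#' defaults are the study priors: drift direction \eqn{\phi \sim U(0, 1)}
#' (radians), drift magnitude \eqn{|\mu| \sim \Gamma(2, 2)}, threshold
#' \eqn{\theta \sim \Gamma(2, 2)}, non-decision time \eqn{\tau \sim
#' \Gamma(1, .4)}, drift variability \eqn{\nu \sim \Gamma(1, 1)} and, when
#' the option angle is free, \eqn{\gamma \sim U(0, \pi)}.
#'
#' @param phi Length-2 \code{c(min, max)} for the uniform drift-direction
#'   prior (radians).
#' @param mu_mag,theta,tau,nu Length-2 \code{c(shape, scale)} gamma
#'   hyperparameters.
#' @param gamma Length-2 \code{c(min, max)} for the uniform option-angle
#'   prior, used when the option angle is a free parameter.
#' @return An object of class \code{"prior_spec"}.
#' @seealso [sample_parameters()], [write_prior_spec()]
#' @export
prior_spec <- function(phi = c(min = 0, max = 1),
                       mu_mag = c(shape = 2, scale = 2),
                       theta = c(shape = 2, scale = 2),
                       tau = c(shape = 1, scale = 0.4),
                       nu = c(shape = 1, scale = 1),
                       gamma = c(min = 0, max = pi)) {
  spec <- list(phi = as.numeric(phi), mu_mag = as.numeric(mu_mag),
               theta = as.numeric(theta), tau = as.numeric(tau),
               nu = as.numeric(nu), gamma = as.numeric(gamma))
  for (nm in c("phi", "gamma")) {
    v <- spec[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[2] <= v[1]) {
      stop("prior for `", nm, "` must be c(min, max) with max > min")
    }
  }
  for (nm in c("mu_mag", "theta", "tau", "nu")) {
    v <- spec[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || any(v <= 0)) {
      stop("prior for `", nm, "` must be c(shape, scale), both positive")
    }
  }
  names(spec$phi) <- names(spec$gamma) <- c("min", "max")
  names(spec$mu_mag) <- names(spec$theta) <- names(spec$tau) <-
    names(spec$nu) <- c("shape", "scale")
  structure(spec, class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  cat(sprintf("  phi    ~ U(%g, %g)  [radians]\n", x$phi[1], x$phi[2]))
  for (nm in c("mu_mag", "theta", "tau", "nu")) {
    cat(sprintf("  %-6s ~ Gamma(shape = %g, scale = %g)\n",
                nm, x[[nm]][1], x[[nm]][2]))
  }
  cat(sprintf("  gamma  ~ U(%g, %g)  [radians, when free]\n",
              x$gamma[1], x$gamma[2]))
  invisible(x)
}

#' Draw simulated-participant parameter sets from the priors
#'
#' Draws \code{n} independent parameter sets. The model class fixes the
#' option angle: \code{"diffusion"} uses \eqn{\gamma = \pi} and scales the
#' drift magnitude by \eqn{\sqrt{2}} (the projection of the accumulation
#' trajectory onto an option vector is longer when the options oppose each
#' other than when they are orthogonal, and the scaling equates effective
#' drift across classes); \code{"accumulator"} uses \eqn{\gamma = \pi/2};
#' \code{"gsr"} draws \eqn{\gamma} from its uniform prior.
#'
#' @param n Number of parameter sets to draw.
#' @param model_class One of \code{"gsr"}, \code{"diffusion"},
#'   \code{"accumulator"}.
#' @param prior A [prior_spec()].
#' @param sigma Diffusion (noise) rate; fixed at 1 by default, the scaling
#'   convention required for identifiability.
#' @param s_v Start-point variability half-width (0 = all trials start at
#'   the origin).
#' @param beta Start-point bias on the balance axis, used only by the
#'   Wiener density utilities; simulations assume a balanced start.
#' @param seed Optional integer seed for a local RNG stream.
#' @return A \code{data.frame} of class \code{"parameter_table"} with one
#'   row per participant and columns \code{phi, mu_mag, theta, tau, nu,
#'   gamma, sigma, s_v, beta, delta, model_class}. \code{delta} is the
#'   signed one-dimensional drift (the projection of the drift vector onto
#'   the balance axis); it is only meaningful for \code{gamma == pi} and is
#'   \code{NA} otherwise.
#' @examples
#' p <- sample_parameters(5, "diffusion", seed = 1)
#' @export
sample_parameters <- function(n,
                              model_class = c("gsr", "diffusion", "accumulator"),
                              prior = prior_spec(),
                              sigma = 1, s_v = 0, beta = 0, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!inherits(prior, "prior_spec")) stop("`prior` must be a prior_spec")
  model_class <- match.arg(model_class)
  with_seed(seed, {
    phi <- runif(n, prior$phi[1], prior$phi[2])
    mu <- rgamma(n, shape = prior$mu_mag[1], scale = prior$mu_mag[2])
    theta <- rgamma(n, shape = prior$theta[1], scale = prior$theta[2])
    tau <- rgamma(n, shape = prior$tau[1], scale = prior$tau[2])
    nu <- rgamma(n, shape = prior$nu[1], scale = prior$nu[2])
    gamma <- switch(model_class,
      diffusion = rep(pi, n),
      accumulator = rep(pi / 2, n),
      gsr = runif(n, prior$gamma[1], prior$gamma[2])
    )
    if (model_class == "diffusion") mu <- mu * sqrt(2)
    delta <- ifelse(gamma == pi, mu * cos(phi), NA_real_)
    structure(
      data.frame(phi = phi, mu_mag = mu, theta = theta, tau = tau, nu = nu,
                 gamma = gamma, sigma = sigma, s_v = s_v, beta = beta,
                 delta = delta, model_class = model_class,
                 stringsAsFactors = FALSE),
      class = c("parameter_table", "data.frame")
    )
  })
}

#' Bayesian urn posterior for the discriminability example
#'
#' Posterior probability that the majority-color hypothesis is true after
#' observing \code{n_draws} consecutive majority-color draws with
#' replacement from one of two complementary urns. With
#' \eqn{p = }\code{p_majority} the majority color's proportion under the
#' favored hypothesis, Bayes' rule gives
#' \deqn{Pr(R|D) = \frac{p^n Pr(R)}{p^n Pr(R) + (1-p)^n (1 - Pr(R))}.}
#' The example illustrates why option discriminability maps onto the
#' balance-of-evidence scale of relative-evidence models: the same two
#' draws are far more diagnostic for 90/10 urns than for 55/45 urns.
#'
#' @param p_majority Proportion of the majority color in the favored urn,
#'   in (0, 1).
#' @param n_draws Number of consecutive majority-color draws (>= 0).
#' @param prior_R Prior probability of the favored urn, in (0, 1).
#' @return Posterior probability, a scalar in (0, 1).
#' @examples
#' urn_posterior(0.55, 2)  # just under 0.60
#' urn_posterior(0.90, 2)  # just under 0.99
#' @export
urn_posterior <- function(p_majority, n_draws, prior_R = 0.5) {
  stopifnot(is.numeric(p_majority), p_majority > 0, p_majority < 1,
            is.numeric(prior_R), prior_R > 0, prior_R < 1,
            is.numeric(n_draws), n_draws >= 0)
  num <- p_majority^n_draws * prior_R
  num / (num + (1 - p_majority)^n_draws * (1 - prior_R))
}
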