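#' Experimental design specification
#'
#' A fully crossed design over coherence (stimulus clarity), match
#' (stimulus--option alignment) and discriminability (option--option
#' separability) levels. The application design replicates the study
#' paradigm: 2 coherence x 3 match x 2 discriminability = 12 conditions
#' with 10 trials each, 120 trials per participant.
#'
#' @param coherence_levels,match_levels,discriminability_levels Vectors of
#'   factor levels. The canonical application values are coherence = c(15,
#'   30) (stimulus-orientation SD in degrees), match = c(0, 1/3, 2/3)
#'   (fraction of the way from the option bisector to an option), and
#'   discriminability = c(30, 60) (angular separation between options in
#'   degrees).
#' @param trials_per_condition Trials per condition per participant.
#' @return A \code{"design_spec"}: a data.frame of conditions (one row per
#'   condition, ordered lexicographically by coherence, match,
#'   discriminability) with attribute \code{trials_per_condition}.
#' @examples
#' design_spec()        # the 12-condition application design
#' @export
design_spec <- function(coherence_levels = c(15, 30),
                        match_levels = c(0, 1/3, 2/3),
                        discriminability_levels = c(30, 60),
                        trials_per_condition = 10) {
  stopifnot(trials_per_condition >= 0)
  grid <- expand.grid(discriminability = discriminability_levels,
                      match = match_levels,
                      coherence = coherence_levels)
  grid <- grid[order(grid$coherence, grid$match, grid$discriminability), ]
  grid <- grid[, c("coherence", "match", "discriminability")]
  rownames(grid) <- NULL
  grid$condition <- paste0("c", format(grid$coherence), "_m",
                           format(round(grid$match, 3)), "_d",
                           format(grid$discriminability))
  grid$condition <- gsub(" ", "", grid$condition)
  structure(grid, class = c("design_spec", "data.frame"),
            trials_per_condition = trials_per_condition)
}

#' @rdname design_spec
#' @export
application_design <- function() design_spec()

#' Proportion of stimulus samples favoring the correct option
#'
#' Under the wrapped-normal stimulus model, each screen update draws an
#' orientation around a mean that sits \code{match_level} of the way from
#' the option bisector toward the correct option. A sample favors the
#' option whose orientation it is closer to, i.e. the correct option when
#' the sample falls on its side of the bisector. Computed from the wrapped
#' normal by summing over wrap-around images.
#'
#' @param match_level Fraction in [0, 1] of the bisector-to-option angle.
#' @param half_angle Half the angular separation between the options,
#'   radians.
#' @param stim_sd Stimulus orientation SD, radians.
#' @return Probability that a sample favors the correct option.
#' @export
favor_proportion <- function(match_level, half_angle, stim_sd) {
  stopifnot(match_level >= 0, match_level <= 1, stim_sd > 0)
  mu <- match_level * half_angle
  k <- -3:3  # wrap-around images; ample for stimulus SDs well below pi
  sum(pnorm((pi - mu + 2 * pi * k) / stim_sd) -
      pnorm((0 - mu + 2 * pi * k) / stim_sd))
}

#' Accumulator drift pair from a match manipulation
#'
#' The accumulator model has one drift per accumulator, but both are set
#' from a single drift-magnitude parameter: first evaluate the proportion
#' of stimulus samples favoring the correct and incorrect option, multiply
#' each proportion by the drift magnitude, and add an independent drift
#' variability draw to each accumulator. This keeps the parameter count
#' matched with the diffusion model.
#'
#' @param mu_mag Drift magnitude (>= 0).
#' @param match_level Fraction in [0, 1]; 0 is perfectly ambiguous.
#' @param nu Drift variability SD.
#' @param half_angle,stim_sd Stimulus geometry, radians.
#' @param seed Optional seed.
#' @return Named numeric vector \code{c(correct, incorrect)} with
#'   attribute \code{"proportion"} (the correct-option sample proportion).
#' @export
accumulator_drifts_from_match <- function(mu_mag, match_level, nu = 0,
                                          half_angle = pi / 12,
                                          stim_sd = pi / 12, seed = NULL) {
  stopifnot(mu_mag >= 0)
  p <- favor_proportion(match_level, half_angle, stim_sd)
  with_seed(seed, {
    d <- c(correct = p * mu_mag + rnorm(1, 0, nu),
           incorrect = (1 - p) * mu_mag + rnorm(1, 0, nu))
    attr(d, "proportion") <- p
    d
  })
}

#' Map factor levels to condition-wise parameter sets
#'
#' Resolves one parameter set per design condition from per-level base
#' values. The application mapping lets drift direction vary with match
#' (3 levels), threshold and option angle vary with discriminability (2
#' levels each), and drift magnitude vary with coherence (2 levels) and
#' match (upper two levels only; the mean drift is fixed at 0 in the
#' lowest-match condition, where the stimulus favors neither option on
#' average), while non-decision time, drift variability and start-point
#' variability are shared across conditions. That mapping has 14 free
#' parameters: 3 + 2 + 2 + 2x2 + 3.
#'
#' @param base A list with elements \code{phi} (one value per match
#'   level), \code{theta} and \code{gamma} (one per discriminability
#'   level), \code{mu_mag} (matrix coherence x upper-match levels, or a
#'   single value when the design has one level of each factor),
#'   \code{tau}, \code{nu}, \code{s_v} (scalars), and optionally
#'   \code{model_class}.
#' @param design A [design_spec()].
#' @return A \code{"condition_map"}: data.frame with one row per
#'   condition carrying the resolved parameters, with attributes
#'   \code{n_free} (free-parameter count) and \code{trials_per_condition}.
#' @examples
#' base <- list(phi = c(0.2, 0.4, 0.8), mu_mag = matrix(2, 2, 2),
#'              theta = c(1.5, 1.5), gamma = c(pi / 2, pi / 2),
#'              tau = 0.3, nu = 0.5, s_v = 0)
#' cm <- build_condition_parameters(base, design_spec())
#' attr(cm, "n_free")  # 14
#' @export
build_condition_parameters <- function(base, design) {
  stopifnot(inherits(design, "design_spec"))
  coh <- sort(unique(design$coherence))
  mat <- sort(unique(design$match))
  dis <- sort(unique(design$discriminability))
  n_mu_free <- length(coh) * max(length(mat) - 1L, 1L)
  if (length(base$phi) != length(mat)) {
    stop("`base$phi` must supply one drift direction per match level")
  }
  if (length(base$theta) != length(dis) || length(base$gamma) != length(dis)) {
    stop("`base$theta` and `base$gamma` must supply one value per ",
         "discriminability level")
  }
  mu <- base$mu_mag
  if (is.null(dim(mu))) mu <- matrix(mu, length(coh), max(length(mat) - 1L, 1L))
  if (!all(dim(mu) == c(length(coh), max(length(mat) - 1L, 1L)))) {
    stop("`base$mu_mag` must be a coherence x upper-match matrix")
  }
  for (f in c("tau", "nu", "s_v")) {
    if (is.null(base[[f]]) || length(base[[f]]) != 1L) {
      stop("`base$", f, "` must be a single shared value")
    }
  }
  mc <- if (is.null(base$model_class)) "gsr" else base$model_class

  rows <- lapply(seq_len(nrow(design)), function(i) {
    ci <- match(design$coherence[i], coh)
    mi <- match(design$match[i], mat)
    di <- match(design$discriminability[i], dis)
    lowest_match <- length(mat) > 1L && mi == 1L
    data.frame(
      condition = design$condition[i],
      coherence = design$coherence[i], match = design$match[i],
      discriminability = design$discriminability[i],
      phi = base$phi[mi],
      mu_mag = if (lowest_match) 0 else mu[ci, if (length(mat) > 1L) mi - 1L else 1L],
      theta = base$theta[di], gamma = base$gamma[di],
      tau = base$tau, nu = base$nu, s_v = base$s_v,
      sigma = if (is.null(base$sigma)) 1 else base$sigma,
      model_class = mc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # tau and nu are always free and shared; s_v counts as free only when the
  # mapping actually uses start-point variability (the estimation model),
  # so the single-condition mapping has the five generative parameters
  # plus gamma = 6 and the application mapping has 14.
  n_free <- length(base$phi) + n_mu_free + length(base$theta) +
    length(base$gamma) + 2L + as.integer(base$s_v != 0)
  structure(out, class = c("condition_map", "data.frame"),
            n_free = n_free,
            trials_per_condition = attr(design, "trials_per_condition"))
}

#' Draw an application-model parameter set from the priors
#'
#' Samples the 14-parameter condition mapping for one simulated
#' participant. Condition-varying parameters reuse the single-condition
#' priors: each drift magnitude is Gamma(2, 2) (scaled by sqrt(2) for the
#' diffusion class), each threshold Gamma(2, 2), each drift direction
#' U(0, 1), tau Gamma(1, .4) and nu Gamma(1, 1). The option angle is pi
#' (diffusion), pi/2 (accumulator) or U(0, pi) per discriminability level
#' (gsr). The start-point variability prior is not part of the stated
#' family set; a U(0, min(theta)/2) cap is used and documented as a
#' placeholder.
#'
#' @param model_class "diffusion", "accumulator" or "gsr".
#' @param design A [design_spec()].
#' @param prior A [prior_spec()].
#' @param with_s_v Draw start-point variability (\code{TRUE} for the
#'   estimation model); \code{FALSE} fixes s_v = 0 as in the
#'   classification simulations, which assume a balanced start.
#' @param seed Optional seed.
#' @return A list shaped for [build_condition_parameters()].
#' @export
sample_application_parameters <- function(model_class = c("gsr", "diffusion",
                                                          "accumulator"),
                                          design = design_spec(),
                                          prior = prior_spec(),
                                          with_s_v = FALSE, seed = NULL) {
  model_class <- match.arg(model_class)
  coh <- sort(unique(design$coherence))
  mat <- sort(unique(design$match))
  dis <- sort(unique(design$discriminability))
  with_seed(seed, {
    mu <- matrix(rgamma(length(coh) * max(length(mat) - 1L, 1L),
                        shape = prior$mu_mag[1], scale = prior$mu_mag[2]),
                 length(coh), max(length(mat) - 1L, 1L))
    if (model_class == "diffusion") mu <- mu * sqrt(2)
    theta <- rgamma(length(dis), shape = prior$theta[1],
                    scale = prior$theta[2])
    gam <- switch(model_class,
                  diffusion = rep(pi, length(dis)),
                  accumulator = rep(pi / 2, length(dis)),
                  gsr = runif(length(dis), prior$gamma[1], prior$gamma[2]))
    list(phi = runif(length(mat), prior$phi[1], prior$phi[2]),
         mu_mag = mu, theta = theta, gamma = gam,
         tau = rgamma(1, shape = prior$tau[1], scale = prior$tau[2]),
         nu = rgamma(1, shape = prior$nu[1], scale = prior$nu[2]),
         s_v = if (with_s_v) runif(1, 0, min(theta) / 2) else 0,
         model_class = model_class)
  })
}

#' Simulate a full dataset over a design
#'
#' Simulates \code{trials_per_condition} trials for every condition of the
#' design, resampling the across-trial drift variability each trial. For
#' the accumulator class, condition drifts are built with the
#' single-parameter proportion rule (see
#' [accumulator_drifts_from_match()]): the drift along each option
#' direction is the proportion of stimulus samples favoring it times the
#' condition's drift magnitude.
#'
#' @param cond_map A [build_condition_parameters()] result.
#' @param trials_per_condition Overrides the design's trial count if
#'   given.
#' @param dt,t_max,keep_trace,seed As in [simulate_trials()].
#' @return A trial table (data.frame) with condition labels and factor
#'   levels attached to each trial.
#' @export
simulate_dataset <- function(cond_map, trials_per_condition = NULL,
                             dt = 0.001, t_max = 10, keep_trace = FALSE,
                             seed = NULL) {
  stopifnot(inherits(cond_map, "condition_map"))
  npc <- if (is.null(trials_per_condition)) {
    attr(cond_map, "trials_per_condition")
  } else trials_per_condition
  if (is.null(npc)) stop("unresolved trials_per_condition")
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(cond_map)), function(i) {
      par <- as.list(cond_map[i, , drop = FALSE])
      if (identical(par$model_class, "accumulator")) {
        # single-parameter drift construction: phi chosen so the drift
        # vector projects p*mu on the correct and (1-p)*mu on the other
        p <- favor_proportion(par$match, half_angle =
                                (par$discriminability / 2) * pi / 180,
                              stim_sd = par$coherence * pi / 180)
        mu_A <- p * par$mu_mag
        mu_B <- (1 - p) * par$mu_mag
        par$phi <- atan2(mu_B, mu_A)
        par$mu_mag <- sqrt(mu_A^2 + mu_B^2)
      }
      tr <- simulate_trials(par, npc, dt = dt, t_max = t_max,
                            keep_trace = keep_trace)
      k <- nrow(tr)
      tr$condition <- rep(par$condition, k)
      tr$gamma <- rep(par$gamma, k)
      tr$coherence <- rep(par$coherence, k)
      tr$match <- rep(par$match, k)
      tr$discriminability <- rep(par$discriminability, k)
      tr
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "cond_map") <- cond_map
    out
  })
}
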