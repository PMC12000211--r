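# Small constructors shared across test files.

# A fully specified parameter list (no prior draws involved).
fixed_par <- function(phi = 0.3, mu_mag = 1, theta = 2, tau = 0, nu = 0,
                      gamma = pi, sigma = 1, s_v = 0,
                      model_class = if (isTRUE(all.equal(gamma, pi)))
                        "diffusion" else "gsr") {
  list(phi = phi, mu_mag = mu_mag, theta = theta, tau = tau, nu = nu,
       gamma = gamma, sigma = sigma, s_v = s_v, model_class = model_class)
}

# Normalized end-of-trial balance of evidence (projection difference per
# stimulus update) for a simulated trial table.
normalized_balance <- function(trials, gamma) {
  trials <- trials[!trials$censored, ]
  (trials$x * (1 - cos(gamma)) - trials$y * sin(gamma)) / trials$n_steps
}

# Hand-built 6-trial table: 4 correct, 2 errors, known RTs.
six_trial_table <- function() {
  data.frame(rt = c(0.4, 0.5, 0.6, 1.0, 0.8, 1.2),
             correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
             censored = FALSE)
}

# Single-condition design with N trials (one level of each factor).
single_condition_design <- function(n_trials = 50) {
  design_spec(coherence_levels = 15, match_levels = 2 / 3,
              discriminability_levels = 60,
              trials_per_condition = n_trials)
}
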