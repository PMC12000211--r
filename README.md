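# gsracc — geometric evidence accumulation for two-alternative choice

Evidence accumulation models dominate the analysis of choice and
response-time data, but their two main families are hard to tell apart:
**relative-evidence** models (random walk / diffusion decision models)
track the balance of support between two options, while
**absolute-evidence** models (racing accumulators) track support for each
option independently. The two families mimic each other's accuracy and RT
predictions closely, so fitting one of them and interpreting its
parameters quietly presupposes the very representation that is at issue.

`gsracc` is for cognitive modellers who want to *test* that
presupposition. It implements both families as special cases of one
two-dimensional stochastic accumulation process in which the choice
options are unit vectors separated by an angle γ:

* γ = π — options are polar opposites; the process is a 1-D diffusion
  between boundaries ±θ (relative evidence),
* γ = π/2 — options are orthogonal; the process is a pair of racing
  diffusions (absolute evidence),
* γ free — a continuum of geometric (GSR) representations in between.

Evidence accumulates as `dX = μ dt + σ dW` in the plane; the support for
an option is the projection of the state onto its direction vector, and
the first projection to reach θ triggers the choice (RT = decision time
+ τ). On top of the simulator the package provides four
model-discrimination methods:

1. **Accumulated-evidence profiles** — the distribution of the normalized
   end-of-trial balance of evidence, with Sarle's bimodality coefficient
   `B = (g² + 1) / (k + 3(n−1)²/((n−2)(n−3)))`, two-boundary Wiener
   first-passage densities, the continuous ±θ/t profile, and K-L–based
   identification of γ over a model grid with cubic-spline interpolation.
2. **Discriminability parameterization** — condition maps sending
   coherence → |μ|, match → φ, discriminability → (γ, θ), including the
   14-parameter 12-condition application model.
3. **Amortized model classification** — a neural network trained on
   simulated participants (15- or 96-input summary layouts) that returns
   the posterior probability of the accumulator model.
4. **Amortized parameter estimation** — a regression network recovering
   the generative parameters (log-scale outputs, so estimates are
   positive), including γ itself.

## Worked example

Simulate one accumulator-model participant, summarize, and inspect:

```r
library(gsracc)

urn_posterior(0.55, 2)   # 0.599: two draws from barely discriminable urns
urn_posterior(0.90, 2)   # 0.988: the same two draws, highly discriminable

par <- sample_parameters(1, "accumulator", seed = 5)
round(as.data.frame(par)[, c("phi","mu_mag","theta","tau","nu","gamma")], 3)
#    phi mu_mag theta  tau    nu gamma
#  1 0.2  4.298 1.767 0.22 2.442 1.571

tr <- simulate_trials(par, 200, seed = 105)
head(tr[, c("choice", "rt", "correct", "censored")], 4)
#   choice        rt correct censored
# 1      B 0.7993314   FALSE    FALSE
# 2      A 0.7013314    TRUE    FALSE
# 3      A 0.3433314    TRUE    FALSE
# 4      A 0.5353314    TRUE    FALSE

round(summarize_single_condition(tr), 3)
#           acc  rt_min_correct    rt_min_error rt_mean_correct   rt_mean_error
#         0.805           0.343           0.393           0.683           0.728
#   q10_correct     q30_correct     q50_correct     q70_correct     q90_correct
#         0.419           0.482           0.556           0.672           0.968
#     q10_error       q30_error       q50_error       q70_error       q90_error
#         0.479           0.577           0.644           0.750           1.078
```

This participant responded correctly 80.5% of the time with mean correct
RT 0.68 s; the 15 slots are exactly the feature vector the classification
network consumes. Training a classifier and estimating γ follow the same
pattern:

```r
ts  <- generate_training_set("classify", n_sims = 2000, n_trials = 100, seed = 1)
clf <- train_classifier(ts, seed = 2)
clf$validation$accuracy                  # held-out proportion correct
classify(clf, summarize_single_condition(tr))  # P(accumulator | data)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/gsracc.R` (subcommands `fixtures`, `simulate`, `summarize`,
`profile`, `fit-gamma`, `train-classifier`, `classify`,
`train-estimator`, `estimate`).

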