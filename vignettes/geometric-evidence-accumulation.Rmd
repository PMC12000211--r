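---
title: "Geometric evidence accumulation: models, discrimination methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric evidence accumulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two-alternative forced-choice behavior is classically explained by two
families of evidence accumulation models. *Relative-evidence* models
(random walks, the diffusion decision model) track the balance of support
between the options: evidence for A is evidence against B, and a response
is triggered when the balance reaches a criterion. *Absolute-evidence*
models (racing accumulators) track support for each option independently
and respond when either accumulator reaches its own criterion. The two
families mimic each other closely on accuracy and response-time data,
which is the problem this package addresses.

`gsracc` implements both as special cases of a single two-dimensional
process. The choice options are unit direction vectors `u_A` and `u_B`
separated by an angle $\gamma$, the model-identity parameter:

* $\gamma = \pi$ — the options oppose each other; the projection of the
  state onto `u_A` is minus its projection onto `u_B`, and the process is
  a one-dimensional diffusion between two parallel boundaries (relative
  evidence).
* $\gamma = \pi/2$ — the options are orthogonal; the two projections are
  independent coordinates and the process is a pair of racing diffusions
  (absolute evidence).
* intermediate $\gamma$ — a continuum of partially coupled
  representations; $\gamma$ below $\pi/2$ expresses mutual excitation
  between similar options.

The accumulation state evolves as a two-dimensional Brownian motion with
drift: each Euler–Maruyama step adds `drift * dt` plus an isotropic
Gaussian increment with standard deviation `sigma * sqrt(dt)` per
coordinate. The support for an option is the scalar projection of the
state on its direction vector (`project()`), and the first projection to
reach the threshold $\theta$ triggers the choice. Reported response time
adds the non-decision time $\tau$.

The frame is canonical — `u_A` along the positive x-axis, `u_B`
counter-clockwise by $\gamma$ — because a global rotation of the plane is
unidentifiable; fixing it makes every output reproducible.

## Parameters, units, and priors

| parameter | meaning | units | prior / default |
|---|---|---|---|
| $\phi$ | drift direction | radians from `u_A` | $U(0, 1)$ |
| $|\mu|$ | drift magnitude | evidence / s | $\Gamma(2, 2)$ (shape–scale) |
| $\theta$ | threshold | evidence units | $\Gamma(2, 2)$ |
| $\tau$ | non-decision time | s | $\Gamma(1, .4)$ |
| $\nu$ | across-trial drift variability (SD) | evidence / s | $\Gamma(1, 1)$ |
| $\gamma$ | option angle | radians | $U(0, \pi)$ when free |
| $\sigma$ | diffusion (noise) rate | evidence / $\sqrt{s}$ | fixed at 1 |
| $s_v$ | start-point variability half-width | evidence units | 0 |
| $\beta$ | start bias (Wiener utilities only) | fraction of boundary span | 0.5 |

Notes on choices the literature leaves open:

* **Units of $\phi$.** The $U(0,1)$ drift-direction prior is interpreted
  in radians (a sub-range of the first quadrant), consistent with
  $\gamma$ being in radians. This is configurable through `prior_spec()`.
* **$\sqrt{2}$ drift scaling.** When the diffusion class
  ($\gamma = \pi$) is compared against the accumulator class, its drift
  magnitude is multiplied by $\sqrt 2$ after the Gamma draw. Opposed
  option vectors double the length of the projection of a drift step
  relative to orthogonal ones over matched coordinates; the scaling
  equates effective drift so that the classifier cannot separate the
  classes on a trivial speed difference.
* **$\sigma = 1$.** Only two of drift, threshold and noise are
  identifiable; fixing the noise rate at 1 is the scaling convention used
  throughout.
* **Start points.** The diffusion class draws its start uniformly on the
  balance axis in $[-s_v, s_v]$; the accumulator and free-angle classes
  draw an independent uniform start in $[0, s_v]$ per accumulator, which
  projects to a triangular balance distribution peaked at zero. Both
  default to $s_v = 0$ (a balanced start), because the two families do
  not agree on the shape of the start distribution and a matched
  comparison should not hinge on it.
* **$s_v$ prior.** The full application model draws
  $s_v \sim U(0, \min(\theta)/2)$. This prior is a documented placeholder:
  no principled family is established for it, and the cap at half the
  smallest threshold keeps start points strictly inside the boundaries.
* **Drift variability.** $\nu$ is implemented as a zero-mean Gaussian
  perturbation resampled each trial — added to the one-dimensional drift
  for the diffusion class, and independently along each option direction
  otherwise, which is the standard convention when no family is stated.

## Simulation conventions

* `dt = 0.001` s and `t_max = 10` s by default. First crossings are
  detected on the discrete grid with no sub-step interpolation; a
  convergence test (choice probabilities at `dt = 0.01` vs `dt = 0.001`
  within Monte-Carlo error at $n = 10^5$) guards the choice. The known
  residual is a first-passage-time bias of order $\sigma\sqrt{dt}$
  (crossings inside a step are missed), which is why the mean-RT test
  uses a finer step.
* Same-step double crossings are broken by the larger projection; exact
  ties by a fair coin from the trial's stream.
* Trials that reach `t_max` are recorded with a censoring flag, never an
  error; summaries exclude them, and corpus generation resamples a
  participant whose cells would otherwise be empty (the count is
  reported).
* Every stochastic function takes an explicit `seed` argument and runs
  under a local RNG stream, restoring the caller's state; nothing depends
  on hidden global state.

## Condition mappings

The application design crosses 2 coherence (stimulus-orientation SD, 15
or 30 degrees) x 3 match (0, 1/3, 2/3 of the way from the option bisector
to an option) x 2 discriminability (30 or 60 degrees of option
separation) levels, 10 trials each — 120 trials per participant.
`build_condition_parameters()` maps factor levels onto parameters:
coherence scales $|\mu|$, match sets $\phi$, discriminability sets
$\gamma$ and $\theta$. Drift magnitude is fixed at zero in the
lowest-match condition (the stimulus favors neither option on average),
and $\tau$, $\nu$, $s_v$ are shared across conditions, giving the
14-parameter application model (3 + 2x2 + 2 + 2 + 3).

For the accumulator class the two racing drifts come from one magnitude
parameter: the proportion $p$ of stimulus samples favoring the correct
option (wrapped-normal orientation model, `favor_proportion()`) gives
drifts $p|\mu|$ and $(1-p)|\mu|$ before the variability draw. This keeps
the parameter count matched between classes. The wrapped normal is
evaluated by summing over $\pm 2\pi k$ images, ample for orientation SDs
far below $\pi$.

## Accumulated-evidence profiles

The profile is the distribution, across trials, of the end-of-trial
balance of evidence (projection difference $comp_A - comp_B$), divided by
the number of stimulus updates when normalized. Relative-evidence
stopping censors balanced states, so the normalized profile is bimodal
with a central gap and inflated variance; absolute-evidence stopping
yields a profile close to the generating stimulus distribution.

Two conventions matter here:

* **Profiles are formed at the stimulus-update resolution.**
  `simulate_discrete_trials()` steps the walk one stimulus update at a
  time (unit time base; $\theta$ and $\sigma$ in per-sample evidence
  units), because the profile's divisor is the number of updates a
  decision-maker actually saw. At millisecond resolution the same
  construction divides by thousands of micro-steps, which crushes the
  profile toward zero and washes out the bimodality that the
  stopping-rule argument is about; at update resolution decisions take
  tens of samples and the diagnostic features survive. The continuous
  construction (`ddm_continuous_profile()`, support $\pm\theta/t$
  weighted by the Wiener first-passage densities) is exposed separately
  and cross-checked against the simulator's choice probabilities.
* **Bimodality depends on the regime.** Sarle's coefficient
  $B = (g^2+1) / (k + 3(n-1)^2/((n-2)(n-3)))$ uses bias-adjusted
  (SAS-style) skewness and excess kurtosis, matching the printed
  n-correction term. $B$ benchmarks: 1/3 for a normal sample, 5/9 for a
  uniform one, 1 for a two-point distribution. Because heavy
  within-cluster tails raise kurtosis, $B$ of a relative-evidence profile
  is largest when decisions take a handful of updates (drift-threshold
  product around 2–4 per-sample units) and can fall below the normal
  benchmark when trial lengths spread over orders of magnitude. The
  ordering test (relative-evidence $B$ above accumulator $B$ at matched
  parameters) is therefore pinned to a moderate regime
  ($\theta = 2$, $|\mu| = 1$ per sample) rather than asserted globally.

K-L identification of $\gamma$ compares the observed profile with
simulated profiles on a shared grid of 61 equal-width bins spanning the
pooled support, with additive smoothing of $1/(n \cdot bins)$ on the
reference (both configurable; no convention is established for either).
The divergence is interpolated over the $\gamma$ grid (evenly
$\pi/8 \dots \pi$) with a cubic spline and minimized by dense evaluation
over $10^4$ points, which avoids derivative-root edge cases; a minimizer
clipping to the grid edge is flagged.

The two-boundary Wiener first-passage density is evaluated by series
expansion with small-time/large-time representation switching, each
series truncated to an absolute tolerance of $10^{-7}$; it is verified
against quadrature (total mass 1 within $10^{-4}$) and the closed-form
absorption probability.

## Amortized inference

Both networks are trained on simulated participants summarized by fixed
layouts: 15 inputs for a single condition (mean accuracy; minimum and
mean RT for corrects and errors; five RT quantiles .1/.3/.5/.7/.9 per
response type) and 8 inputs per condition over a design (mean accuracy,
mean correct/error RT, five quantiles of the pooled RT distribution),
hence 96 for the 12-condition design. The pooled-quantile reading is the
only one under which 8 x 12 gives 96; minimum RT belongs to the 15-slot
layout only. Quantiles are linear interpolation of order statistics
(type 7). When a response type is empty, its slots are copied from the
other side and the vector is flagged — copying keeps inputs finite
without inventing a sentinel scale; the flag is not appended as an input
so layout widths stay at 15/96.

The networks themselves are single-hidden-layer perceptrons (`nnet`),
with inputs standardized by training-set mean/SD, BFGS optimization and
weight decay for regularization, and a 10% held-out split for reported
accuracy. The classifier has a probabilistic output (accumulator
posterior; labels 0 = diffusion, 1 = accumulator); the estimator
regresses the log-transformed generative parameters and exponentiates on
inversion so every estimate is positive, with $\gamma$ clipped to
$(0, \pi]$. Hidden size (default 40), decay ($10^{-3}$) and iteration
budget are configurable. A deeper architecture is a drop-in replacement
behind the same training/evaluation surface; at the corpus sizes used
here the single hidden layer already saturates the summary-vector signal,
and weight decay takes the regularizing role that early stopping plays in
deep-learning pipelines.

## What the generator emulates — and what it does not

The synthetic participants replicate the study conditions: generative
priors as tabled above, the $\sqrt 2$ scaling for the diffusion class,
single-condition corpora at N = 100–200 trials, and the 12-condition
design at 10 trials per condition (120 per participant; 34 participants
give 4080 trials in the fixture shape). The generator does **not**
emulate: post-decision stimulus frames contaminating traces during the
non-decision period (an optional lag is deliberately omitted by default),
attention lapses or fast guesses, leaky or ballistic accumulation,
collapsing boundaries, or multi-alternative choice. Passing tests
therefore show that the methods work when the generating process is in
the model family — parameter recovery and classification accuracy on real
data additionally depend on deviations the generator excludes.

## Problem sizes

The package's own test suite and acceptance script run at reduced,
seeded scales chosen to keep the full pipeline honest while remaining
desk-sized: the single-condition classifier uses $2 \times 10^4$
participants per class at N = 100 trials (held-out split 10%); the
estimator recovery run uses $8 \times 10^3$ participants at N = 100; the
desk-scale classifier properties (accuracy monotone in trials, chance
accuracy under shuffled labels) use $1.5\!-\!2 \times 10^3$ per class;
profile sweeps use $10^4$ trials per setting. Full-scale corpora
($10^5$–$5 \times 10^5$ participants) are a matter of passing larger
`n_sims`; the code path is identical.

## Known limitations

* The balance-axis coordinate is the projection difference; for
  $\gamma = \pi$ its magnitude is twice the one-dimensional position.
  All profile statistics used are scale-invariant, but absolute balance
  values should be read with that convention in mind.
* The Euler scheme's first-passage bias shortens no RT but lengthens all
  of them by $O(\sigma\sqrt{dt})$; analyses that need unbiased mean RTs
  should reduce `dt`.
* `nnet`'s BFGS is deterministic given the seed but can land in local
  optima for very small corpora; the toy-problem tests use enough
  capacity and iterations that this does not bite.
* The K-L fit degrades near the $\gamma = \pi$ edge of the grid (the
  spline cannot bracket the minimum); such fits carry a boundary flag.
* Fixture participants whose slowest condition is fully censored are
  resampled, so the realized prior over fixtures is the generative prior
  conditioned on producing at least one response per condition.
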