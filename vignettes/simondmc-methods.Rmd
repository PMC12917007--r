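---
title: "Modelling conflict in the Simon task: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conflict in the Simon task: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

In the visual Simon task a participant responds to a non-spatial target
feature (here, the color of a lateralized square) while the task-irrelevant
stimulus location primes the spatially corresponding response.  Responses
are faster and more accurate when stimulus side and required response side
match (congruent) than when they mismatch (incongruent) — the Simon effect.

`simondmc` implements the diffusion model for conflict tasks (DMC), a
dual-route evidence-accumulation account of this effect.  A single
diffusion process $X(t)$ accumulates the *superimposed* drift of two
routes:

* a controlled, target-based route with constant drift rate $\mu_T$
  (evidence units per ms), and
* an automatic, distractor-based route whose expected activation is a
  rescaled gamma density,
  $$E[X_A(t)] = A\, e^{-t/\tau} \left(\frac{t\,e}{(\alpha - 1)\tau}\right)^{\alpha-1},$$
  rising from 0 to its peak amplitude $A$ at
  $t_{\mathrm{peak}} = (\alpha - 1)\tau$ and decaying back to zero.  Its
  drift contribution $\mu_D(t)$ is the time derivative of $E[X_A(t)]$,
  entering with $+$ on congruent and $-$ on incongruent trials.

The process starts at $z \sim$ symmetric-beta$(\alpha_s, \alpha_s)$
rescaled to $(-b, b)$, evolves as
$X(t{+}dt) = X(t) + \mu(t)\,dt + \sigma \sqrt{dt}\, N(0,1)$ and is
absorbed at $+b$ (correct) or $-b$ (error).  Reaction time adds a normal
residual (non-decision) time $N(\mu_R, \sigma_R)$, truncated at zero.
Because the distractor input is transient, fast responses are sampled
while distractor activation is strong and slow responses after it has
decayed: the model therefore predicts the characteristic *delta-plot*
shapes — the congruency effect across RT percentiles declines late when
the pulse peaks early ($\tau = 25$ ms) and rises-then-falls when it peaks
later ($\tau = 40$ ms).

### The delayed-target-onset variant

`onset_delay` ($\delta$) starts target accumulation only $\delta$ ms after
stimulus onset, while the distractor pulse clock runs from $t = 0$ — so
distractor activation is already decaying when target evidence begins.
This represents the hypothesis that greater visual eccentricity delays
early target processing rather than weakening it.  Simulated delays slow
responses and *reduce* the Simon effect relative to $\delta = 0$, and shift
the delayed cell's delta plot *below* the undelayed one — the opposite
offset direction from a strength-based account in which far targets have
lower $\mu_T$ and/or higher $A$.  One caveat found while validating the
implementation: the reduction is not strictly monotone in $\delta$ for
early-peaking pulses (with $\tau = 25$ ms the mean effect at
$\delta = 80$ ms exceeds that at $\delta = 40$ ms, because what matters is
the residual distractor activation profile after onset, not the delay per
se).  The tests therefore pin the `delayed < undelayed` ordering for every
positive delay, and monotone decline only across a moderate grid with a
later-peaking pulse.

## Parameters, units, defaults

| parameter | meaning | unit | demonstration value | condition-average estimates |
|---|---|---|---|---|
| `mu_t` | target drift rate | evidence/ms | 0.7 | 0.54–0.61 |
| `amp` | distractor peak amplitude | evidence | 30 | 12.9–16.6 |
| `tau` | distractor scale (= peak time for $\alpha$=2) | ms | 25 / 40 | 79–103 |
| `aa_shape` | pulse shape $\alpha$ | — | 2 (fixed) | 2 (fixed) |
| `bound` | boundary $b$ | evidence | 70 | 75–77 |
| `res_mean`, `res_sd` | residual time | ms | 300, 30 | 332–349, 29–32 |
| `sp_shape` | starting-point beta shape $\alpha_s$ | — | 3 | 3.48–3.54 |
| `sigma` | diffusion constant | evidence/$\sqrt{\mathrm{ms}}$ | 4 (fixed) | 4 (fixed) |

`reference_params()` returns the four condition-average sets (two
experiments × near/far eccentricity); `demo_params()` the demonstration
set.  Integration uses a fixed Euler–Maruyama step `dt = 1` ms — the
conventional step for this model class — and `t_max = 2000` ms, matching
the behavioral response deadline; a trial that reaches no boundary by
`t_max` is a non-response, as in the task.

### Numerical choices and degenerate inputs

* Two absorbing boundaries at $\pm b$.  The published description mentions
  only the correct boundary $b$, but error responses require a lower
  boundary; the symmetric $\pm b$ convention of the original DMC is used.
* The starting-point range is taken as the full $(-b, +b)$ interval.  The
  published description says starting points vary symmetrically around
  zero between two endpoints without relating them to $b$; the full-range
  convention follows the original DMC.  Narrower ranges can be emulated
  with larger `sp_shape`.
* Residual-time draws are truncated at zero; at realistic parameter values
  the truncation probability is below $10^{-20}$ and has no practical
  effect.
* Drift is evaluated at the left endpoint of each integration step; the
  $t \to 0$ limit of the distractor drift is defined by continuity
  ($A e/\tau$ for $\alpha = 2$).
* The simulator uses its own seeded RNG stream (64-bit Mersenne Twister
  with a ziggurat normal sampler), so a given seed reproduces identical
  trials regardless of R's RNG state; R-level functions draw sub-seeds
  from R's RNG so that one `set.seed()`/`seed =` argument controls a whole
  pipeline.

## Distributional summaries

All analyses run on three summaries per condition:

* **CDF quantiles** of correct RTs on the nine deciles 10%…90%, by linear
  interpolation of order statistics with plotting positions
  $p_k = (k - 0.5)/n$ (`stats::quantile` type 5).  The interpolation rule
  is not dictated by the source analyses; it is pinned here (and in the
  tests) because small samples are mildly sensitive to it, and the
  sensitivity is worth knowing rather than assuming away.
* **Conditional accuracy functions** over five equal-count RT bins
  (stable ties, remainders spread over the earliest bins).  Five bins is
  the convention in this literature; the count is configurable.
* **Delta plots**: per-decile incongruent-minus-congruent quantile
  differences of correct RTs, plotted against the two quantiles' average.
  Group delta plots average deltas and abscissae percentile-wise across
  participants, which preserves shared location shifts exactly.

## Fitting

`fit_condition()` fits one participant × one eccentricity condition, both
congruencies jointly, minimizing a pooled weighted RMSE over the 18 CDF
quantile residuals (ms) and 10 CAF residuals (proportion ×
`caf_weight`).  The published analysis states only that errors and RT
distributions were fitted simultaneously by RMSE; the pooled form and the
weight are this package's documented reconstruction.  `caf_weight = 300`
(0.01 accuracy ≙ 3 ms) makes the two blocks contribute comparably both at
typical misfit and in sampling noise: at a few hundred observed trials,
CAF bin accuracies carry binomial SEs around 0.02–0.03 while CDF deciles
carry 6–9 ms, so neither block can dominate the objective with noise.
The weight was selected by parameter-recovery benchmarking over
candidates 200–500 and is a configuration knob.

The optimizer is bound-constrained differential evolution with binomial
crossover (0.9), population 10× the number of free parameters,
differential weight drawn uniformly in [0.5, 1] each generation,
reflection at the bounds, at most 110 generations with early stop after
25 generations without relative improvement above 10⁻⁴.  The default
mutation strategy is local-to-best/1 — each candidate moves toward the
current best plus a scaled random difference vector — which is the default
of the differential-evolution package the reference fits used and, in
recovery benchmarks here, converges to lower objective values than plain
rand/1 at the same evaluation budget (rand/1 remains available).  The
original fits used unpublished optimizer settings; these defaults are
declared approximations and are all recorded in the returned
`fit_result`.  Box bounds are generous
brackets around the published condition means (`amp` [0, 40], `tau`
[5, 300], `mu_t` [0.1, 1.0], `bound` [20, 150], `res_mean` [200, 800],
`res_sd` [5, 100], `sp_shape` [2, 4]).

Two variance-reduction devices stabilize the stochastic objective:

* **Common random numbers** (`crn = TRUE`): one simulation seed is reused
  across all candidate evaluations within a fit, so candidates are
  compared on a fixed surface rather than through independent Monte-Carlo
  jitter.
* **Antithetic variates** (`antithetic = TRUE`): inside cost evaluations,
  odd trials mirror their predecessor's noise.  Marginals are unchanged;
  quantile and accuracy estimates get cheaper and less noisy.  Data
  *generation* never uses antithetic pairing, because real trials are
  independent and the synthetic data should carry realistic sampling
  noise.

Each cost evaluation simulates 5,000 trials (2,500 per congruency).  This
budget, with the population and generation limits above, makes a single
participant-condition fit take roughly half a minute on one CPU core —
the package's chosen balance between objective smoothness and the
practicality of fitting dozens of synthetic participants in a recovery
study.

### What recovery studies show — and what they cannot

`recover_parameters()` is the validity standard: simulate participants at
known parameters (560 post-exclusion trials each, as in the emulated
design), fit each, and compare recovered means to the generating values.
At this trial count the objective has a pronounced ridge: single-participant
estimates trade decision noise against residual noise (`res_sd` is
attracted downward, `mu_t` and `bound` upward), and `tau` has a long
right tail — a minority of datasets place their objective minimum at
pulse scales two to three times the generating value, because the decay
phase of the distractor pulse is constrained mainly by the noisiest part
of the data (the slow tail of the RT distribution).  These are properties
of the estimator at this sample size, not optimizer failures: refitting
the same dataset from different optimizer seeds lands on the same
minimum.  Across-participant means land within roughly 10% of the
generating `mu_t` and `amp` and within roughly 20–25% for `tau` — the
level at which the published analyses interpret these parameters
(condition means and paired differences).  Individual estimates should
not be over-read, and `tau` means should be read with its skew in mind.

## The synthetic-data generator

`simulate_experiment()` emulates the two deposited designs: 12 blocks × 56
trials, 2 colors × 2 sides × 2 eccentricities, seven repetitions of each
of the eight displays per block with eccentricity randomized within blocks
(Experiment 1), or fourteen repetitions of each of four displays with
eccentricity alternating across blocks, the starting level counterbalanced
by participant parity (Experiment 2).  A 2 s deadline is inherited from
`t_max`.  The color-to-response mapping is fixed (red→left, blue→right)
with optional parity counterbalancing; congruency is mapping-invariant in
aggregate.

Between-participant variability: per-parameter truncated-normal draws
around the condition means, with SDs defaulting to the published standard
errors scaled to person level ($SE \cdot \sqrt{96}$), and a shared
person-level deviate correlating each parameter's near and far values
($r = 0.8$ by default — the same people tend to be slow or cautious in
both conditions; the exact value is a modelling choice, not an estimate).
`apply_exclusions()` reproduces the stated preparation: participants under
80% accuracy removed, the first two blocks dropped, no-response trials
dropped, and error trials additionally dropped for RT analyses.

What the generator does *not* emulate: practice and fatigue trends,
sequential (trial-history) effects, fixation/feedback timing, RT
contamination (anticipations, attention lapses), and any deviation of real
residual-time distributions from truncated normality.  Passing tests on
synthetic data therefore validate the *inference machinery* — that the
pipeline recovers the structure the model itself generated — not the
model's adequacy for any particular empirical dataset.

## Group-level inference

* 2 × 2 repeated-measures ANOVA (congruency × eccentricity) on mean RT
  and percentage error, with partial $\eta^2$; at 2 × 2 the interaction F
  is identical to the squared paired t on the difference of congruency
  differences, which the tests exploit as an algebraic oracle.
* Paired t tests with Cohen's $d$ (mean difference / SD of differences)
  for fitted-parameter comparisons between eccentricity conditions.
* The delta-plot shift test — per-percentile paired t tests on
  $\Delta_{\mathrm{far}} - \Delta_{\mathrm{near}}$ with Holm correction,
  plus an overall mean-offset paired t — is a reconstruction: the original
  supplementary analysis is described only as "additional delta plot
  analyses".  Both pieces are reported so users can apply their preferred
  multiplicity standard.

## Problem sizes used in the shipped analyses

The package's own demonstrations and checks use: 30,000–50,000 trials per
congruency for simulation suites (Monte-Carlo SE of a mean RT well under
1 ms), 10 synthetic participants per generating condition for recovery
studies, and 6–12 participants for end-to-end pipeline demonstrations.
These sizes are the package's choices for routine verification; all of
them are arguments, and larger runs only tighten the Monte-Carlo error.

## Known limitations

* No closed-form first-passage densities: everything is simulation-based,
  so fitted objectives are stochastic and two fits agree only up to
  Monte-Carlo and optimizer tolerance (both are seeded and reported).
* The weighted-RMSE form, DE hyperparameters, and shift-test procedure are
  documented reconstructions of underspecified originals (see above).
* Single-participant estimates at 560 trials are weakly identified along
  a decision-noise/residual-noise ridge; interpret condition means and
  within-participant contrasts, not individuals.
* The model variant space is deliberately narrow: no leaky or competing
  accumulators, no collapsing bounds, no within-trial variability beyond
  the starting point.
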