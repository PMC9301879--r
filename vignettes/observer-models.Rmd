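---
title: "Causal-inference observer models for categorical audiovisual localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-inference observer models for categorical audiovisual localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventriloquo)
```

## The task and the apparatus

`ventriloquo` analyzes categorical audiovisual localization experiments of the
ventriloquism family. An observer faces four loudspeakers at -15, -5, +5 and
+15 degrees azimuth, with LEDs mounted at the same positions, and reports the
perceived location of auditory (A), visual (V), or audiovisual (AV) stimuli by
pressing one of 12 buttons spanning the width of the array. Two blocks of 240
trials are run: Block 1 crosses the four A and four V positions factorially in
its 160 AV trials (spatial discrepancies from -30 to +30 degrees), and Block 2
presents a constant +10 degree discrepancy (V right of A) to induce cumulative
recalibration.

The button-to-degree mapping is not uniquely determined by the physical
description, so the package adopts one consistent convention: 12 uniformly
spaced button centers at `(i - 6.5) * 10/3` degrees, which places buttons 2,
5, 8 and 11 exactly at the four speaker positions, with one flanking button
beyond each outer speaker. One response unit therefore equals 10/3 degrees.
Continuous quantities are binned into buttons by half-open intervals
`[center - spacing/2, center + spacing/2)`, with the outer buttons absorbing
everything beyond their edges; the half-open convention fixes deterministic
tie-breaking at bin edges.

## The observer models

All models assume that stimuli at `(s_A, s_V)` elicit noisy internal
sensations

$$x_A \sim N(s_A + \Delta_A, \sigma_A), \qquad
  x_V \sim N(s_V + \Delta_V, \sigma_V),$$

where the biases $\Delta_m$ and noise SDs $\sigma_m$ are the likelihood
parameters of modality $m$. A Gaussian location prior $N(\mu_P, \sigma_P)$ is
shared by both modalities, and the causal prior $P_c$ is the prior
probability that the two cues share a common cause.

Under a common cause ($C = 1$), the joint density of the sensations
marginalized over the shared source has the closed form

$$p(x_A, x_V \mid C=1) =
  \frac{1}{2\pi\sqrt{\sigma_A^2\sigma_V^2 + \sigma_A^2\sigma_P^2 +
  \sigma_V^2\sigma_P^2}}
  \exp\!\left[-\tfrac12
  \frac{(x_V - x_A)^2\sigma_P^2 + (x_A-\mu_P)^2\sigma_V^2 +
        (x_V-\mu_P)^2\sigma_A^2}
       {\sigma_A^2\sigma_V^2 + \sigma_A^2\sigma_P^2 + \sigma_V^2\sigma_P^2}
  \right],$$

while under independent causes ($C = 2$) it factorizes into the two marginal
Gaussians with variances $\sigma_m^2 + \sigma_P^2$. Bayes' rule over the two
structures gives the posterior probability of a common cause. The optimal
(squared-error) location estimates are precision-weighted averages: the fused
estimate combines $x_A$, $x_V$ and the prior mean; the segregated estimates
shrink each sensation toward the prior mean alone. Both closed forms are
verified in the test suite against trapezoid quadrature of the defining
integrals, and the fused estimate is checked to converge to pure
reliability weighting as $\sigma_P \to \infty$.

Seven observers are implemented:

* **CI-MA, CI-PM, CI-MS** — Bayesian causal inference with three decision
  strategies. Model averaging returns the posterior-weighted average of
  the fused and segregated estimates. Probability matching picks the fused
  estimates when the posterior exceeds a uniform draw $\xi$; a single draw is
  shared by the A and V responses of a trial, so the trial commits to one
  causal structure (the two response equations reference the same $\xi$).
  Model selection applies a fixed 0.5 threshold; a posterior of exactly 0.5
  segregates, matching the weak inequality of the selection rule.
* **FF, SG** — fixed-structure baselines with the location prior: forced
  fusion always uses the fused estimate, segregation always the
  prior-shrunk unimodal estimates.
* **FFnp, SGnp** — the same baselines without priors: reliability-weighted
  averaging and the raw sensations, respectively.

Model predictions for an AV stimulus pair are Monte-Carlo histograms: 10,000
simulated trials (the publication-grade default) pushed through the
estimation-and-decision chain and binned into the 12 buttons. No motor or
response noise is added beyond binning — the models describe no further noise
stage. All model arithmetic is in degrees; button space enters only at the
binning step.

## Three-step fitting

**Step 1.** The unimodal likelihood parameters $(\Delta_m, \sigma_m)$ are fit
per block and modality to the unimodal trials by maximum likelihood on a
discretized Gaussian: a trial with stimulus $s$ and response button $b$
contributes the probability mass of $N(s + \Delta, \sigma)$ on $b$'s
interval, with the outer buttons integrating to $\pm\infty$. Errors are
pooled across the four stimulus locations into one Gaussian per modality.
This mirrors the conventional unimodal-fit procedure even though the
prior-carrying observers would predict slightly prior-shrunk unimodal
responses — a deliberate inconsistency retained from the procedure being
reimplemented. Maximization uses a dense grid followed by L-BFGS-B within
$\Delta \in [-30, 30]$, $\sigma \in [0.25, 40]$ degrees.

**Step 2.** Each family's free prior parameters are fit to the Block 1 AV
trials by maximizing the multinomial log-likelihood
$\sum_i n_i \ln p_i$ summed over the 16 stimulus pairs and both response
modalities (the multinomial coefficient is constant across models and is
dropped). The predicted $p_i$ come from the Monte-Carlo simulation; to make
the stochastic objective deterministic in the parameters, one fixed set of
draws (sensations and $\xi$) is generated per fit and reused for every
parameter evaluation (common random numbers) — a bounded quasi-Newton search
needs a stable objective. Monte-Carlo zeros are floored at
`1/(2 * n_sim)` inside the logarithm, without renormalization, so observed
counts in empty predicted bins cost a large but finite penalty. The search
space is $\mu_P \in [-20, 20]$, $\sigma_P \in [1, 60]$ degrees,
$P_c \in [0, 1]$ — spanning the stimulus range and plausible prior widths —
divided into 10 even portions (11 values per parameter, so 1,331 starting
sets for CI models and 121 for FF/SG); the best grid point initializes an
L-BFGS-B refinement (numerical derivatives, step 0.01 in native units), and
the grid optimum is retained if refinement fails to improve it. Families are
compared by BIC $= -2\hat{LL} + k\ln N$ with $k$ counting only the
parameters fitted in this step (CI: 3, FF/SG: 2, FFnp/SGnp: 0; the Step 1
parameters are shared by all models and cancel in comparisons) and $N$ the
number of localization responses entering the likelihood (Block 1: 160
trials x 2 responses = 320). Ties resolve toward fewer parameters, then a
fixed family order.

**Step 3.** The best Block 1 family is refit to the Block 2 AV trials with
the Block 2 unimodal parameters from Step 1; the best model is assumed
stable across blocks while its parameters may change. No model comparison is
performed.

`fit_families()` exploits that the three CI families share everything up to
the decision step and that FF/SG reuse the fused/segregated estimates: the
grid search computes the shared quantities once per candidate, which makes
fitting all seven families much cheaper than seven independent fits while
returning results identical to per-family `fit_model()` calls.

## Effect statistics

Responses are coded 1-12 and referenced to per-location baselines: the mean
coded response over the 10 unimodal Block 1 trials of that modality and
location. Signed errors (response minus baseline; positive = rightward) are
converted to degrees by the 10/3 button spacing.

* **VE** (ventriloquism effect): mean Block 1 AV error on
  rightward-discrepancy trials minus leftward-discrepancy trials, per
  response modality. Zero-discrepancy trials are excluded — they are neither
  rightward nor leftward — and trials are pooled with equal weight rather
  than weighting discrepancy magnitudes equally.
* **VAEi** (immediate aftereffect): the same contrast on unimodal Block 1
  trials classified by the nearest preceding AV trial's discrepancy
  (interjacent unimodal trials skipped; the design guarantees no +-30
  predecessors and 8 trials per cell).
* **VAEc** (cumulative aftereffect): mean unimodal Block 2 error against the
  Block 1 baselines.
* **Precision**: SD of the unimodal Block 1 errors per modality — because
  errors are location-centered this pools the per-location response SDs.

A useful symmetry: reflecting all stimuli and responses about the midline
leaves VE and VAEi unchanged (the contrast swaps conditions while the errors
negate) and flips the sign of VAEc. The property tests assert exactly this.

Group-level inference uses Welch's heteroscedastic ANOVA with Satterthwaite
degrees of freedom (`stats::oneway.test`), Games-Howell pairwise comparisons
(Welch t statistics referred to the studentized range; undefined below 2
denominator df, where `NA` is returned), one-tailed one-sample t tests
against zero with Holm correction applied within each effect type's six
group-by-modality tests (the correction family is configurable), and
Spearman rank correlations between effect pairs overall and within groups.
Default one-sided directions follow the phenomenology — auditory effects
tested as greater than zero, visual effects as less than zero (bias toward
the A location).

## The synthetic cohort generator

`simulate_cohort()` generates complete datasets with the structure the
analysis assumes. AV responses come from the ground-truth observer's full
chain; unimodal responses are binned draws from
$N(s + \Delta_m, \sigma_m)$ with the active block's likelihood parameters,
consistent with the Step 1 fitting model.

The default archetypes encode the minimal parameter structure reproducing
the qualitative pattern the analysis is designed to detect. All groups share
a CI-PM observer with $\sigma_A = 6$, $\Delta = 0$, $\mu_P = 0$,
$\sigma_P = 25$ degrees, $P_c = 0.5$. Visual noise is 2 (SC), 2.5 (DC) and
3.5 (CC) degrees — visual impairment raises visual noise but leaves vision
more precise than audition. Cumulative recalibration is planted as Block 2
likelihood-bias shifts: $\Delta_A$ +3 degrees in SC and CC, +2 in DC, and
additionally $\Delta_V$ -2 degrees in CC only — the visual recalibration
that distinguishes the congenital-cataract group. Per-participant parameters
are jittered with 15% relative Gaussian spread; the response order is
counterbalanced and ignored by all analyses.

Static observers carry no trial history, so they cannot produce an immediate
aftereffect. The generator therefore includes an explicit single-trial
recalibration term — an extension beyond the observer models, clearly
separate from them: each unimodal response mean is shifted by a gain times
the preceding AV discrepancy. Bare `participant_profile()` objects default
this gain to zero; the archetypes enable an auditory gain of 0.08, chosen
a priori so that the planted contrast (2 x 0.08 x 15 = 2.4 degrees) clearly
exceeds cohort-level sampling noise (~0.7 degrees SEM) while staying within
the single-trial recalibration magnitudes reported for this paradigm.

What the generator does *not* emulate: response lapses and attention
failures, motor errors, drifting biases within a block, reaction times, and
any dependence of recalibration on time or trial number beyond the
single-trial term. Passing recovery tests on these cohorts therefore shows
that the pipeline inverts its own generative assumptions at realistic noise
levels — not that real observers satisfy those assumptions.

## Numerical choices and problem sizes

Sequence construction is constructive rather than rejection-based: the 160
AV trials are shuffled, then 8 A and 8 V trials are attached in short runs
behind randomly chosen AV carriers of each eligible discrepancy category, so
the preceding-AV balance and the no-unimodal-after-±30 rule hold by
construction (a validation pass and retry budget guard the contract). Every
generator and fit takes an explicit seed and is a pure function of it; the
package never touches the global RNG state.

The reduced preset `fit_config_test()` (2,000 simulations per pair, 5 grid
values per parameter, refinement capped at 20 iterations) is used for the
package's own recovery experiments — parameter recovery to within the stated
tolerances and family recovery by BIC — while `fit_config()` keeps the
publication-grade 10,000/11 settings. The recovery experiments in the test
suite use 160 AV trials x 2 responses per dataset, 20 replicates per
condition, and 40-trial unimodal fits, the sizes a desk-scale validation of
this design calls for. One caveat identified by the recovery experiments:
with a wide location prior ($\sigma_P \gtrsim 25$ degrees) the FF and SG
observers are practically indistinguishable from FFnp/SGnp at these sample
sizes, and BIC rightly prefers the parsimonious variant; the model-recovery
experiment therefore generates the fixed-structure observers with a clearly
expressed prior ($\sigma_P = 5$).

## Known limitations

* The continuous-estimate binning assumes no response noise; observers whose
  button presses add motor scatter will inflate fitted $\sigma_m$.
* Step 1's pooled, unshrunk Gaussian is internally inconsistent with the
  prior-carrying observers (kept deliberately, see above).
* The multinomial objective is a step function of the parameters at finite
  `n_sim`; L-BFGS-B can stall on flat patches, in which case the grid
  optimum is returned and flagged (`convergence = 52`).
* Bayes-factor hypothesis tests are out of scope; only frequentist group
  tests are provided.
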