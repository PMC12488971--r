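---
title: "Learning progress, difficulty and engagement: models and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning progress, difficulty and engagement: models and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpengage)
```

## The scientific question

Why do people enjoy some games more than others? A family of theories
predicts an inverted U: enjoyment and engagement peak at intermediate
difficulty, because intermediate difficulty offers the most *learning
progress* — the per-step improvement of the player's model of the
environment. `lpengage` implements the computational side of a study of this
idea across two gamified experiments and three game-level datasets: agents
that track their own learning progress, a threshold rule that converts
learning-progress trajectories into simulated engagement, the statistical
analyses (negative-binomial mixed regressions, disparity statistics,
polynomial model comparison), and synthetic-cohort generators that let every
analysis be exercised and validated without access to behavioral data.

## The two environments

**Number machines.** A machine draws numbers from a Gaussian with a fixed
mean, uniform on [20, 80], and a fixed variance drawn from
{0.1, 1, 10, 100, 1000}; draws below 1 or above 100 are resampled, and the
displayed number is an integer. The variance is the difficulty: a variance
0.1 machine repeats itself, a variance 1000 machine is close to noise.

**Point grids.** A 30×30 landscape is drawn from a zero-mean Gaussian
process with RBF kernel `k(x, x') = exp(-||x - x'||^2 / (2 lambda^2))` on
0-based integer lattice coordinates, with lengthscale lambda from
{0.25, 0.5, 1, 2, 4, 8, 16}. The latent surface is rescaled affinely so the
tiles span exactly 40 points with the minimum uniform on [5, 35] (values
therefore in [5, 75]); the displayed tile value is rounded to an integer,
the continuous surface is kept alongside. Sampling uses a Cholesky factor of
the 900×900 kernel with 1e-8 diagonal jitter, cached per lengthscale.

## The two learners

**Kalman mean tracker.** The agent's belief about a machine's mean is
Gaussian with mean `mu` and variance `var` (prior 50 and 10). Each
observation `x` updates with gain `K = var / (var + obs_var)`; the agent
uses the machine's true variance as observation noise. Learning progress of
a step is the absolute mean update `|mu' - mu|`. Before observing, its
expectation is available in closed form,
`K * sqrt(2 (var + obs_var) / pi)`, which gives a deterministic,
reproducible proxy (`expected_learning_progress()`).

**GP function learner.** The grid learner performs noise-free GP regression
with the generating kernel and matched lengthscale over the revealed tiles
and predicts every other tile; its error is the mean squared difference
from the ground truth over unrevealed tiles. Learning progress of a step is
the decrement of that error.

## The stopping rule and its numerics

Engagement is simulated by interacting until learning progress falls below
a threshold (default 0.5), with forced minima of 3 guesses per machine and
5 tiles per grid and caps of 200 and 900. The step that triggers the stop is
counted.

Three numerical choices deserve explanation:

* **Machines, deterministic vs Monte-Carlo.** The deterministic mode
  thresholds the expected absolute update and reproduces the closed-form
  precision recursion exactly; with prior variance 10 and threshold 0.5 the
  five design variances give 3, 3, 5, 7, 3 guesses — an inverted U whose
  endpoints sit on the floor. The Monte-Carlo mode thresholds the realized
  |update|. The two modes do *not* share an argmax: a realized update is a
  noisy version of its expectation, so conditions whose expected progress
  hovers just above the threshold stop early with probability about one
  half per step, and the Monte-Carlo peak sits at a lower variance
  (variance 10 rather than 100 for prior 10). Both modes produce the
  interior maximum; tests assert the shape, not the argmax. At thresholds
  where the deterministic proxy collapses to the floor entirely (e.g. 1.0
  with prior 10), only the Monte-Carlo mode can display the shape.

* **Grids, error scale.** The threshold of 0.5 for the grid learner lives
  on the raw point scale (grids span 40 points; the prediction error starts
  near the field variance, roughly 40–100 points²). On a per-grid
  standardized scale the total variance is 1 and per-step decrements are
  one to two orders of magnitude below 0.5, so every grid would stop at the
  floor and no inverted U could exist. A `scale = "standardized"` option is
  retained for sensitivity analyses.

* **Grids, latent vs displayed values.** The stopping simulation learns the
  continuous pre-rounding surface. Integer rounding adds a noise floor
  (variance 1/12) that the matched-lengthscale GP cannot explain on smooth
  grids; its step-to-step MSE fluctuations sporadically exceed the
  threshold and destroy the interior maximum (measured: with rounded
  values, mean engagement increases monotonically to lambda 16; with the
  latent surface the peak sits at lambda 8 with both endpoints below it).

## The engagement analyses

Per-session counts are modeled with negative-binomial regressions with a
participant random intercept (`lme4::glmer.nb`; participant fixed effects
via `MASS::glm.nb` as an automatic, logged fallback). The condition enters
z-scored, and squared: a negative quadratic detects the inverted U. Because
both experimental designs place their conditions on log-spaced ladders, the
default condition variable is log10(variance) or log2(lengthscale); on the
raw variance scale the five design values z-score to approximately
(-0.51, -0.51, -0.49, -0.28, 1.79), so the linear and squared terms are
nearly collinear and neither is estimable with useful precision.

`fit_count_quadratic()` has a `floor` argument that subtracts the forced
minimum before fitting. The synthetic generator's counts are
`floor + NegBin`, so recovery studies fit the shifted response; `floor = 0`
reproduces the conventional raw-count fit used on behavioral data.

**Difficulty-expectation disparity.** For each machine after the first, the
estimated variance (unbiased sample variance of its emitted numbers) is
compared with the expected variance — the guess-weighted average of the
estimated variances seen so far. The raw-scale difference is the primary
definition. A log10 variant is provided for the log-spaced design; there,
estimated variances are floored at 1/12 (the integer display's rounding
variance — a run of identical displayed numbers carries no spread
information) and the expectation is the guess-weighted *geometric* mean,
since the arithmetic mean is pinned near the largest variance in history
and would place "zero disparity" at the edge of the attainable range.
`fit_disparity_engagement()` scales the disparity by its standard deviation
but does not center it: in a centered parameterization a null linear term
would locate the peak at the sample-mean disparity, whereas the question is
whether the peak sits at zero.

**Level tables.** Calculated difficulty is 1 minus the clear ratio;
enjoyment is the star rate, the like-ratio (upvotes over votes) or the
award count, depending on the schema. For the platformer schema the
expected difficulty of a creator category is the mean calculated difficulty
of the levels in that category (self-calibrating; the original category
mapping is not public). Polynomial fits of enjoyment on z-scored difficulty
are compared by AIC with a margin of 10; a higher degree is adopted only
when it beats the best lower-degree fit by more than the margin (a flat
linear term must not block a clearly better quadratic — symmetric inverted
U's have exactly that structure).

**Manipulation check.** Mean absolute guess error per variance and the
correlation between (log) variance and exact-match counts. The first guess
of each session is excluded: it is made before any emission is observed and
measures the distance between the prior (50) and the machine's mean, not
the machine's difficulty.

## The synthetic cohorts: what they emulate and what they do not

`generate_guessing_cohort()` and `generate_grid_cohort()` produce
participant logs with the structure the analyses assume: sessions drawn
from the experimental designs, guesses from a Kalman tracker (rounded
posterior mean plus integer noise, SD 2 points), reveals uniformly at
random, and per-session counts from
`floor + NegBin(exp(b0 + b1 z + b2 z^2 + ...), theta)` with a participant
random intercept (SD 0.3) and a per-participant interaction budget standing
in for the 10-minute session. The final, budget-interrupted session is
flagged censored and excluded from analyses, mirroring the removal of each
participant's last machine.

Defaults were chosen once, a priori: intercept log(5) above the floor of 3
for machines (about 8 guesses per machine and 14 machines in a 77-guess
budget, matching the reported cohort means), intercept log(31) above the
floor of 5 for grids (about 36 tiles per grid), linear 0.3 and quadratic
-0.5 on the scaled log condition (the curvature implied by a simulated
engagement range of roughly 3 to 7 guesses), magnitude 0.1, dispersion 8.
The disparity-recovery world uses the log10 metric with quadratic -0.25 per
squared decade, baseline log(8) and a 120-guess budget (about 14 machines
of 8.5 guesses): on the raw scale the chi-square measurement noise of the
estimated variance is strongly right-skewed and biases the fitted linear
term away from zero, so a peak-at-zero world is only recoverable on the
log scale.

What a green recovery test establishes: the analysis code identifies the
signs and magnitudes of its own generating process at realistic sample
sizes, with calibrated false-positive rates under the null. What it does
not establish: anything about human strategy heterogeneity, sequential
dependence beyond the budget, level-selection behavior, or the published
coefficient values, which derive from the deposited behavioral data.
Two known biases are deliberate properties of the stated world: the
fixed budget length-biases sampling of participants' random intercepts
(short-session participants contribute more rows), which biases the fitted
*baseline* but not the slope coefficients — recovery is therefore asserted
for slopes; and estimated-variance noise attenuates disparity curvature.

## Degenerate inputs and tie-breaking

A flat latent surface cannot be rescaled to span 40 and raises. A response
identically at the floor is flagged degenerate rather than fitted. A
disparity table is empty until a participant has a non-first, non-censored
session. Engagement sweeps break peak ties toward the smaller condition
value (relevant for priors so small that every variance stops at the
floor). The GP oracle comparison is meaningful only while the kernel is
numerically nonsingular; on a 5×5 lattice that bounds the lengthscale by
about 4.

## Known limitations

* The mixed NB fit occasionally fails to converge on extreme cohorts; the
  fixed-effects fallback is logged in the result rather than hidden.
* The grid learner knows the generating lengthscale (matched-model
  simulation); lengthscale inference is out of scope.
* Tile choice is uniformly random; no acquisition strategy is modeled.
* The category-to-difficulty mapping for the platformer schema is a
  self-calibrating stand-in for an unpublished mapping.
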