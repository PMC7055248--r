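---
title: "Methods: active-inference simulation and phase-lag analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-inference simulation and phase-lag analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the modelling and analysis methods implemented in
**phasematch**: the generative model of the hand–target phase-matching
task, the generalized-coordinate integration scheme, the wavelet
phase-lag estimator, and the behavioural statistics.  Code chunks are
shown but not evaluated (the simulations take seconds to minutes); every
chunk runs as written.

## The task

A simulated hand tracks an oscillating target by rhythmic grasping.  Two
hidden states evolve in the world: the target's oscillation phase
`x_t`, advancing at a constant rate, and the hand posture `x_h`, driven
by action.  Three sensory channels report sines of these states:

* `target` — the target's visible size, `sin(x_t)`;
* `prop`   — felt hand posture, `sin(x_h)`;
* `vis`    — seen hand posture, `sin(x_h - v)`.

In *incongruent* conditions the seen hand lags the felt hand by a fixed
displacement `v = 0.35` rad (about 117 ms at the task's movement rate);
in congruent conditions `v = 0`.  The agent is instructed to keep either
the seen hand (`VH`) or the felt hand (`RH`) on the target, and
attention is operationalised as the sensory log-precision of a modality:
`HA` raises the instructed channel by one log-unit, `HD` the
non-instructed one.

```{r}
library(phasematch)
task_params()            # study-preset constants
condition_registry()     # the twelve named conditions
```

## Inference and action

The agent runs generalized (predictive-coding) filtering: beliefs about
the hidden states and the displacement cause are held in generalized
coordinates of motion (position, velocity, acceleration; embedding order
3) and descend the variational free energy,

```
mu_dot = D mu - dF/dmu,      a_dot = -dF/da,
```

where `D` is the derivative-shift operator and `F` is the sum of
precision-weighted squared prediction errors ([free_energy()]).  Action
affects free energy only through the true generative process: the
proprioceptive and visual consequences of moving the hand.  Precisions
over generalized orders follow a Gaussian autocorrelation model with
smoothness 0.5 time bins ([autocorr_precision()]).

Two implementation choices deserve emphasis; both are modelling
decisions, not fitted quantities:

* **Joint local linearization.**  Each 1/120 s bin advances the *coupled*
  vector of beliefs, action and world states by one matrix-exponential
  step of the locally linearized joint dynamics
  ([integrate_trial()]).  Closing the perception–action loop within the
  bin is what makes the sensorimotor loop stable at this sampling rate;
  integrating the agent against a frozen world drifts at movement
  reversals.

* **Embedding order 3.**  The sine sensory mapping admits a mirror
  ambiguity (`sin(pi - x) = sin(x)`).  At higher embedding orders the
  realistic incongruent conditions can fall into a spurious
  mirror-image attractor in which beliefs oscillate instead of
  advancing and the hand stalls.  Order 3 (with state log-precision 3)
  is the stable phase-tracking regime for all twelve conditions over
  long multi-cycle trials; `simulate_agent()` documents this default.

```{r}
sim <- simulate_agent("vh_incong_ha", duration = 16)
summary(sim)
plot(sim, which = "sensory")
```

Across the incongruent conditions the instructed modality's absolute
lag orders as `HA < default < HD` in both tasks, and the difference
between the virtual- and real-hand lags always equals the displacement's
time equivalent — attention changes which signal tracks the target, not
the geometry of the conflict.

## Phase-lag estimation

Behavioural and simulated trajectories are phase-compared with a complex
Morlet continuous wavelet transform at the movement frequency
([cwt_phase_lag()]).  Both series are demeaned, transformed
(centre-frequency parameter 6), and the per-sample phase differences are
averaged circularly (resultant vector) over a window that excludes one
wavelet half-support at each edge (cone of influence).  The lag is
reported in seconds, wrapped into half a period.  On pure sinusoids the
estimator recovers imposed shifts to well under one sample at 60 Hz.

```{r}
fs <- 60; t <- seq(0, 32 - 1 / fs, by = 1 / fs)
cwt_phase_lag(sin(pi * (t - 0.5)), sin(pi * t), f0 = 0.5, fs = fs)  # 0.5
```

## Synthetic cohorts and statistics

`generate_cohort()` renders a data-glove cohort with the behavioural
design (24 participants, 4 conditions, 6 trials of 32 s at 60 Hz,
0.5 Hz grasping, 500 ms visual delay when incongruent): per-participant
condition lags, per-trial jitter, per-finger sensor gains and channel
noise, plus 7-point ratings from a latent-Gaussian model.  The `"null"`
preset shares the design with all effects removed, for calibration.

The analysis chain ([analyze_cohort()]) averages the four non-thumb
fingers, estimates per-trial lags, aggregates them by circular mean into
a participant x condition table, and fits:

* a 2 x 2 repeated-measures ANOVA (task x congruence) with
  participant-level error strata; because both factors are two-level,
  every F must equal the squared paired-contrast t, and
  [rm_anova_2x2()] verifies this identity internally;
* Bonferroni-corrected paired post-hoc t-tests;
* Friedman and pairwise Wilcoxon signed-rank tests on the ratings
  (normal approximation, mid-ranks, dropped zeros, continuity
  correction).

```{r}
co <- generate_cohort(cohort_spec("study", seed = 1), dir = "cohort")
res <- analyze_cohort("cohort")
summary(res)
```

On null cohorts the ANOVA's interaction test holds its nominal 5%
type-I rate, and on effect cohorts the injected condition lag means are
recovered within sampling error; both properties are enforced by the
package's acceptance tests.

## Command-line interface

`inst/cli/phasematch.R` wraps three commands — `simulate`, `synth`,
`analyze` — around YAML run configurations; each writes its fully
resolved configuration next to its outputs.

```{r}
# Rscript inst/cli/phasematch.R synth   --out cohort --seed 1
# Rscript inst/cli/phasematch.R analyze --input cohort --out results
```
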