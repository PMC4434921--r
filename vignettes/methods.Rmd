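---
title: "Models, pipeline and design choices in affectrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, pipeline and design choices in affectrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectrl)
```

This vignette is the package's own account of the science it implements:
the task model, the learning model and its hierarchical estimation, the ERP
pipeline, what the synthetic-data generator does and does not emulate, and
the choices made where the design was genuinely open.

## The dynamic reward task

The task presents two pairs of card decks (the "Up" pair A/B and "Down"
pair C/D). Each pair is bound to one prime condition (affective or
neutral) for a whole session; which pair carries which condition is
randomized per schedule, so a simulated cohort is counterbalanced. The two
conditions are interleaved randomly trial by trial, each filling half of
the trials (default 480 + 480 = 960).

Each condition's trials are divided into `n_blocks_per_condition` blocks
(default 6) whose lengths are drawn uniformly from the integer compositions
of the per-condition trial count with every part inside
`block_length_range` (default 70–90). The draw is implemented by sampling
block lengths i.i.d. uniformly on the admissible range and conditioning on
their sum, which is exactly the uniform distribution on the constrained
compositions.

Within a block, the rich and poor decks of a pair pay independent Bernoulli
rewards with probabilities in ratio r:1 summing to `total_reward_prob`
(default 0.60): ratio 6:1 gives 36/70 vs 6/70. The poor probability is
computed as `total - rich`, so the pair sums to the configured total
exactly in floating point. At every block transition the rich side swaps;
the ratio magnitude is redrawn uniformly from `ratio_set` (default {6, 3},
which together with the side swap realizes the four ratios 6:1, 3:1, 1:3,
1:6). Three points were open and are resolved as follows:

* **Totals in the experimental phase.** Only the training phase states the
  60% total explicitly; the experimental ratios are taken to share it,
  since they generalize the training ratios and no other total is given.
* **No baiting.** Rewards are drawn independently per trial and per deck
  and do not persist when uncollected. Ancestor foraging tasks bait
  rewards, but nothing in the task description requires it, and
  independent draws are the simplest consistent scheme.
* **Ratios across the two pairs.** Each condition/pair draws its block
  structure independently; nothing couples the simultaneous pairs.

`realize_rewards()` pre-draws the outcome of *every* deck on every trial,
so an agent's choice merely reveals one of the pre-drawn outcomes; this
makes schedule, outcomes, and behavior separately reproducible from their
seeds.

## The Q-learning / softmax model

Expected values start at `q_init = 0.5` for all decks — the midpoint of
the 0/1 reward range; the value is exposed in `agent_params()` rather than
hard-coded. Only the chosen deck is updated:

$$Q_{c}(t+1) = Q_{c}(t) + \alpha\,\delta(t), \qquad
  \delta(t) = R(t) - Q_{c}(t),$$

and with rewards in {0,1}, `q_init` in [0,1] and α in [0,1] every Q stays
in [0,1]. Choice follows the Boltzmann rule with perseveration β ≥ 0.
`choice_prob()` evaluates the logistic on the non-negative half of its
argument and returns the complement on the other side; this keeps the two
decks' probabilities exact floating-point complements (they sum to 1
bit-exactly) and is stable for arbitrarily large β·Q.

Q values are maintained per deck pair and are **not** reset at block
transitions — the transitions are un-signaled, so the agent cannot know to
reset. The likelihood replays Q from `q_init` given observed choices and
rewards; it never trusts Q values stored in a log. A single (α, β) pair is
shared across both prime conditions per subject; per-condition fits are
obtained by filtering the trial list by condition and fitting each subset,
which the data contract (a plain list of trial logs) makes trivial.

The replay loop is implemented in C++ (Rcpp) because the sampler evaluates
it on the order of 10^5–10^6 times per fit; tests pin it against an
independent R replay oracle at tolerance 1e-12.

## Hierarchical Bayesian estimation

Subject parameters are modeled as draws from group-level normals truncated
to the parameter supports — α_i from N(μ_α, σ_α) on [0,1], β_i from
N(μ_β, σ_β) on [0, ∞). Truncation is required for a well-defined density
at the bounds; the truncation constants (which depend on the group
parameters) are included in the density, so the group-level updates are
correct. Hyper-priors are uniform: U(0,1) for μ_α and σ_α, U(0,10) for
μ_β, U(0,5) for σ_β; the σ priors are read as bounding the *standard
deviation*, not the precision.

The sampler is component-wise random-walk Metropolis within Gibbs with
Gaussian proposals. Proposal scales adapt every 50 iterations during
burn-in (shrinking below 20% acceptance, growing above 50%) and freeze
afterwards, so the retained chain is a valid fixed-kernel Markov chain.
Initialization uses coarse grid maximum-likelihood estimates per subject
(jittered per chain) with hyper-parameters at their sample mean/SD clamped
inside the prior support — this guarantees a finite starting density.
The full protocol settings (3 × 16,000 iterations, 6,000 burn-in, thin 5,
retaining 6,000 of 30,000 post-burn-in draws) are the `mcmc_settings()`
defaults; tests and the study orchestrator use reduced chains
(3 × 2,000–4,000) that recover parameters at desk scale.

Convergence is assessed by the classic Gelman–Rubin potential scale
reduction factor over the retained chains (zero-variance chains are
defined to R-hat = 1 with a warning; a single chain is refused with advice
to split it). Group comparisons use the Wald statistic
$z = (\bar\theta_1 - \bar\theta_2)/\sqrt{s_1^2 + s_2^2}$ over retained
draws with a two-sided normal p-value.

Grid-integration oracle: with one subject, the uniform hyper-priors
integrate out independently for α and β, leaving a two-dimensional
posterior that can be evaluated on a dense grid; the test suite checks the
MCMC posterior mean of α against this oracle within 0.02.

## The ERP pipeline

Filtering uses an order-4 Butterworth bandpass (designed as `butter(2,
band)`, i.e. a 4th-order transfer function) applied forward and backward
(zero phase). The filter is applied to the **continuous** record before
segmentation: a 0.1 Hz highpass has a time constant of seconds and cannot
act inside a 0.8 s epoch — filtering epochs directly leaves DC behind and
shaves several percent off slow components. `bandpass()` accepts epoched
input for completeness, but the canonical path (`preprocess_feedback()`)
is filter → epoch → baseline → reject.

Epochs span −100..700 ms around feedback (−100..500 ms around the prime),
endpoints inclusive at integer-millisecond sampling (801 samples at
1000 Hz); sample times are milliseconds relative to the event. Baseline
correction subtracts the per-epoch, per-channel mean over [−100, 0) ms.
Artifact rejection removes an epoch when *any* channel at *any* sample
exceeds ±50 μV — the criterion is per epoch, not per channel. Eye-blink
correction is not implemented (the recording-system routine it would
replicate is proprietary pattern recognition); threshold rejection is the
only cleaning stage, and the rejection report carries per-label rates.
Re-referencing to averaged mastoids is available as a continuous-stage
operation and is a no-op on reference-free synthetic data.

The three FRN variants are computed on difference waves: General (all
non-reward minus all reward), Expected (expected-omission minus
expected-delivery), Unexpected (unexpected-omission minus
unexpected-delivery), with expectation defined by whether the rich deck
was chosen. Peaks are measured **on the difference wave** (the variant
definitions construct difference waves first and measure those); the
underlying `peak_component()` also works on raw condition averages if the
alternative convention is wanted. The peak is the extreme sample in the
search window (200–400 ms for FRN, 110–200 ms N170, 120–180 ms EEP), ties
broken toward the earliest latency; a flat wave therefore reports the
window start. Sides with fewer than `min_epochs` (default 10) epochs are
reported missing rather than averaged into a fabricated cell.

## The synthetic-data generator

`synth_cohort()` draws subject parameters from the truncated group
normals (inverse-CDF sampling) and plays each subject through an
independent schedule; the generating truth table is returned for recovery
scoring. `synth_epochs()` builds epochs directly — background noise plus a
Gaussian-shaped negativity (center 280 ms, SD 40 ms) added to omission
epochs, scaled per channel so the noise-free difference wave's windowed
negative peak equals the target amplitude. The bump shape and latency are
modeling choices (the results being emulated report only windows and peak
amplitudes); a Gaussian is the simplest shape with a controllable windowed
peak. Prime-locked epochs embed the N170 (negative, 150 ms, SD 20 ms,
occipito-temporal, right-lateralized by default: P7 −4, P8 −5 μV) and the
EEP (positive, 150 ms, SD 15 ms, midline: Fz 3, Cz 2.8, Pz 2.2 μV); these
defaults are plausible magnitudes chosen once, as no numeric component
amplitudes are available for them.

Default FRN targets per group follow the reported General FRN group means
(NN −6.50, AN −7.33, HN −7.23 μV) spread over the fronto-central
topography (Fz 0.90, FCz 1.00, Cz 1.01 of the group value); separate
expected/unexpected targets can be set, in which case the General variant
measures their epoch-weighted mixture.

Background noise defaults to white Gaussian, SD 5 μV at 1000 Hz; a 1/f
option adds realism. White noise keeps the extreme-value behavior of peak
picking analytically checkable: with no embedded component, the measured
"amplitude" of a windowed minimum is not zero but ≈ −2.57 standard
deviations of the difference wave (the expected minimum of ~201 i.i.d.
normals); the tests compare the measured bias against a Monte-Carlo oracle
of exactly that quantity. This bias is also why recovered amplitudes sit
slightly *below* embedded ones at high noise.

What the generator does **not** emulate: volume conduction and channel
covariance (channels are independent), blink/EMG artifact morphology
(rejection is exercised with amplitude outliers only), latency jitter of
components across trials, overlapping components in the feedback window,
and any dependence of EEG on the model's trial-by-trial prediction error.
Passing round trips therefore demonstrate that the pipeline measures what
it is pointed at — not that it would survive every pathology of recorded
EEG.

`synth_feedback_record()` is the continuous counterpart used for full
filter-path round trips: events every 1000 ms, 2000 ms padding, bumps
added over their ±4 SD support.

## Behavioral summaries

PCRD curves are trailing (causal) moving averages of the rich-choice
indicator within block and condition — never across transitions; the
trailing form matches the trial-by-trial accumulation the curves describe.
The acquisition state is block trials 1–20, the steady state the rest;
state means are unsmoothed, and their trial-count-weighted combination
reproduces the overall rich-choice rate exactly. Blocks of 20 or fewer
trials flag an empty steady state rather than silently producing one.

A non-reward run is a maximal streak of non-rewarded choices of the same
deck; by default only streaks terminated by a shift to the other deck are
counted ("runs before shifting"), and `require_shift = FALSE` counts all
streaks. Simulation across matched schedules shows that *higher* β
(stronger perseveration) yields *longer* mean runs under both definitions
— a near-greedy agent only abandons a deck when its value estimate
crosses, while a stochastic agent shifts even after single losses. This is
the direction the package asserts in its tests, and it matches the
association between high perseveration and long non-reward runs in the
behavioral findings the package models.

## Problem sizes and runtime choices

Defaults chosen for the simulation studies in the test suite: cohorts of
8–20 subjects at 160–480 trials each; reduced MCMC (2–3 chains of
400–4,000 iterations) for everything except the bookkeeping check, which
runs the full 3 × 16,000 protocol on a small log; ERP round trips at
200–400 epochs per side. `run_config()` defaults to 3 groups × 12 subjects
× 480 trials with 3 × 2,000 MCMC — a desk-scale study that exercises every
stage; protocol-scale runs use `task_config()` and `mcmc_settings()`
defaults directly.

## Known limitations

* The sampler is random-walk Metropolis; it is adequate for the
  ~2(N+2)-dimensional posteriors here but mixes more slowly than gradient
  samplers, and σ parameters are the slowest components.
* Only the single-(α, β) Q-learning model is implemented — no dual
  learning rates, actor–critic, or model-comparison criteria.
* The ERP stage implements peak measures only; mean-amplitude windows,
  time–frequency measures and scalp statistics are out of scope.
* Epoched-input filtering is supported but physically limited at the
  0.1 Hz edge, as discussed above; use the continuous path when slow
  components matter.
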